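# Fasted-state four-compartment dissolution method, full 215 min protocol
duration_min: 215
withdrawal_mL: 1
step_min: 0.1
compartments:
  - name: stomach
    start_volume_mL: 230   # 30 mL gastric juice + 200 mL water
    residual_mL: 30
    residence_min: 30      # linear emptying
    ph: free               # set by the formulation (2.4 if nonbuffered)
  - name: duodenum
    start_volume_mL: 33
    residence_min: 10
    ph: 6.5
  - name: jejunum
    start_volume_mL: 33
    residence_min: 60
    ph: 6.6
  - name: ileum
    start_volume_mL: 33
    residence_min: 90
    ph: 7.4
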