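# Truncated fasted-state method: terminated directly after the 43 min sample
duration_min: 43
withdrawal_mL: 1
step_min: 0.1
compartments:
  - name: stomach
    start_volume_mL: 230
    residual_mL: 30
    residence_min: 30
    ph: free
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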