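dm:
- '250.00'
- '250.01'
- E10.9
- E11.9
- E13.9
micro:
- '250.40'
- '250.60'
- '357.2'
- '362.01'
- '583.81'
- E10.40
- E11.21
- E11.22
- E11.311
- E11.42
macro:
- '410.90'
- '414.01'
- '433.10'
- '440.9'
- '443.9'
- I21.9
- I25.10
- I63.9
- I70.209
- E11.51
dm_related:
- '585.9'
- N18.9
- H35.00
- '354.0'
cpt:
- '92250'
- '93922'
- '66821'
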