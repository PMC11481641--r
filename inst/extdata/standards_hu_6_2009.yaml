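profile: hu_6_2009
description: >
  Groundwater quality limits for shallow municipal wells following the
  Hungarian joint decree 6/2009 (IV. 14.) KvVM-EuM-FVM. The ideal value is
  0 for all concentrations and 7 for pH; the pH limit is the upper bound of
  the permissible 6.5-8.5 range.
parameters:
- code: pH
  unit: ''
  ideal: 7.0
  limit: 8.5
  lower_limit: 6.5
- code: EC
  unit: uS/cm
  ideal: 0.0
  limit: 2500.0
- code: NH4
  unit: mg/L
  ideal: 0.0
  limit: 0.5
- code: NO2
  unit: mg/L
  ideal: 0.0
  limit: 0.5
- code: NO3
  unit: mg/L
  ideal: 0.0
  limit: 50.0
- code: PO4
  unit: mg/L
  ideal: 0.0
  limit: 0.5
- code: COD
  unit: mg/L
  ideal: 0.0
  limit: 4.5
- code: Na
  unit: mg/L
  ideal: 0.0
  limit: 200.0
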