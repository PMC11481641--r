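description: 'Default synthetic monitoring design: 40 wells in a 2 km x 2 km extent,
  sampled 2013 and 2017-2019, 2021-2022, dropout to 37 and 34 wells; per-year marginals
  calibrated to the published descriptive statistics; sewerage boundary year 2014.'
n_wells: 40
extent:
- 0.0
- 2000.0
- 0.0
- 2000.0
years:
- 2013
- 2017
- 2018
- 2019
- 2021
- 2022
n_per_year:
- 40
- 40
- 40
- 40
- 37
- 34
boundary_year: 2014
range_m: 500.0
sill_fraction: 0.5
crs: EPSG:23700
calibration:
- year: 2013
  parameter: pH
  mean: 8.25
  q25: 7.92
  q75: 8.56
  'n': 40
  min: 7.23
  max: 9.42
- year: 2013
  parameter: EC
  mean: 3032.65
  q25: 1950.25
  q75: 4310.0
  'n': 40
  min: 340.0
  max: 7670.0
- year: 2013
  parameter: NH4
  mean: 0.69
  q25: 0.43
  q75: 0.87
  'n': 40
  min: 0.23
  max: 1.89
- year: 2013
  parameter: NO2
  mean: 0.31
  q25: 0.05
  q75: 0.42
  'n': 40
  min: 0.02
  max: 1.28
- year: 2013
  parameter: NO3
  mean: 187.83
  q25: 50.16
  q75: 341.77
  'n': 40
  min: 2.36
  max: 564.82
- year: 2013
  parameter: PO4
  mean: 1.22
  q25: 0.37
  q75: 1.75
  'n': 40
  min: 0.07
  max: 4.07
- year: 2013
  parameter: COD
  mean: 6.85
  q25: 4.03
  q75: 8.05
  'n': 40
  min: 2.4
  max: 18.2
- year: 2013
  parameter: Na
  mean: 237.91
  q25: 132.18
  q75: 312.78
  'n': 40
  min: 8.9
  max: 653.2
- year: 2017
  parameter: pH
  mean: 7.51
  q25: 7.29
  q75: 7.74
  'n': 40
  min: 7.02
  max: 8.3
- year: 2017
  parameter: EC
  mean: 2845.78
  q25: 1871.25
  q75: 3507.5
  'n': 40
  min: 876.0
  max: 9290.0
- year: 2017
  parameter: NH4
  mean: 0.53
  q25: 0.24
  q75: 0.64
  'n': 40
  min: 0.08
  max: 3.42
- year: 2017
  parameter: NO2
  mean: 0.2
  q25: 0.02
  q75: 0.17
  'n': 40
  min: 0.01
  max: 1.86
- year: 2017
  parameter: NO3
  mean: 142.65
  q25: 37.65
  q75: 221.08
  'n': 40
  min: 4.46
  max: 616.64
- year: 2017
  parameter: PO4
  mean: 0.39
  q25: 0.09
  q75: 0.58
  'n': 40
  min: 0.03
  max: 1.54
- year: 2017
  parameter: COD
  mean: 7.65
  q25: 5.24
  q75: 9.9
  'n': 40
  min: 2.9
  max: 17.68
- year: 2017
  parameter: Na
  mean: 377.94
  q25: 154.15
  q75: 422.48
  'n': 40
  min: 75.8
  max: 2254.2
- year: 2018
  parameter: pH
  mean: 8.0
  q25: 7.68
  q75: 8.29
  'n': 40
  min: 7.21
  max: 8.87
- year: 2018
  parameter: EC
  mean: 2637.8
  q25: 1874.25
  q75: 3190.0
  'n': 40
  min: 1140.0
  max: 6380.0
- year: 2018
  parameter: NH4
  mean: 0.65
  q25: 0.33
  q75: 0.68
  'n': 40
  min: 0.14
  max: 3.97
- year: 2018
  parameter: NO2
  mean: 0.21
  q25: 0.01
  q75: 0.3
  'n': 40
  min: 0.0
  max: 1.37
- year: 2018
  parameter: NO3
  mean: 109.76
  q25: 23.73
  q75: 153.03
  'n': 40
  min: 6.95
  max: 538.3
- year: 2018
  parameter: PO4
  mean: 0.65
  q25: 0.22
  q75: 0.86
  'n': 40
  min: 0.03
  max: 2.76
- year: 2018
  parameter: COD
  mean: 7.16
  q25: 3.59
  q75: 8.48
  'n': 40
  min: 1.1
  max: 36.8
- year: 2018
  parameter: Na
  mean: 352.37
  q25: 182.32
  q75: 447.77
  'n': 40
  min: 97.39
  max: 1828.03
- year: 2019
  parameter: pH
  mean: 7.21
  q25: 6.97
  q75: 7.42
  'n': 40
  min: 6.81
  max: 7.9
- year: 2019
  parameter: EC
  mean: 2773.43
  q25: 1511.25
  q75: 3792.5
  'n': 40
  min: 695.0
  max: 8910.0
- year: 2019
  parameter: NH4
  mean: 0.52
  q25: 0.29
  q75: 0.62
  'n': 40
  min: 0.12
  max: 3.37
- year: 2019
  parameter: NO2
  mean: 0.26
  q25: 0.02
  q75: 0.31
  'n': 40
  min: 0.0
  max: 1.94
- year: 2019
  parameter: NO3
  mean: 170.73
  q25: 43.1
  q75: 244.85
  'n': 40
  min: 7.61
  max: 645.5
- year: 2019
  parameter: PO4
  mean: 0.48
  q25: 0.14
  q75: 0.6
  'n': 40
  min: 0.04
  max: 2.14
- year: 2019
  parameter: COD
  mean: 7.68
  q25: 4.58
  q75: 10.12
  'n': 40
  min: 1.66
  max: 16.65
- year: 2019
  parameter: Na
  mean: 383.68
  q25: 185.37
  q75: 477.99
  'n': 40
  min: 52.14
  max: 2019.77
- year: 2021
  parameter: pH
  mean: 7.23
  q25: 7.06
  q75: 7.36
  'n': 37
  min: 6.84
  max: 8.0
- year: 2021
  parameter: EC
  mean: 4128.92
  q25: 1808.0
  q75: 5930.0
  'n': 37
  min: 980.0
  max: 14830.0
- year: 2021
  parameter: NH4
  mean: 0.47
  q25: 0.25
  q75: 0.51
  'n': 37
  min: 0.12
  max: 1.4
- year: 2021
  parameter: NO2
  mean: 0.24
  q25: 0.03
  q75: 0.31
  'n': 37
  min: 0.01
  max: 1.54
- year: 2021
  parameter: NO3
  mean: 164.52
  q25: 33.19
  q75: 185.0
  'n': 37
  min: 16.59
  max: 829.18
- year: 2021
  parameter: PO4
  mean: 0.37
  q25: 0.09
  q75: 0.48
  'n': 37
  min: 0.04
  max: 1.53
- year: 2021
  parameter: COD
  mean: 4.21
  q25: 2.1
  q75: 4.14
  'n': 37
  min: 0.97
  max: 23.18
- year: 2021
  parameter: Na
  mean: 319.88
  q25: 157.42
  q75: 362.57
  'n': 37
  min: 80.53
  max: 1396.35
- year: 2022
  parameter: pH
  mean: 7.27
  q25: 7.08
  q75: 7.5
  'n': 34
  min: 6.95
  max: 7.8
- year: 2022
  parameter: EC
  mean: 3664.21
  q25: 2163.75
  q75: 4623.75
  'n': 34
  min: 1396.0
  max: 11700.0
- year: 2022
  parameter: NH4
  mean: 0.64
  q25: 0.38
  q75: 0.77
  'n': 34
  min: 0.14
  max: 2.47
- year: 2022
  parameter: NO2
  mean: 0.2
  q25: 0.04
  q75: 0.25
  'n': 34
  min: 0.0
  max: 1.24
- year: 2022
  parameter: NO3
  mean: 296.1
  q25: 76.1
  q75: 377.27
  'n': 34
  min: 9.64
  max: 1186.05
- year: 2022
  parameter: PO4
  mean: 0.24
  q25: 0.1
  q75: 0.32
  'n': 34
  min: 0.03
  max: 0.89
- year: 2022
  parameter: COD
  mean: 2.19
  q25: 1.71
  q75: 2.58
  'n': 34
  min: 0.99
  max: 5.11
- year: 2022
  parameter: Na
  mean: 153.51
  q25: 94.9
  q75: 205.26
  'n': 34
  min: 21.71
  max: 295.77
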