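demography:
  total_population: 8978929.0
  frac_aged_50_74: 0.3222
  smoking_rate: 0.2076
  mean_entry_age: 58.0
epidemiology:
  annual_incidence_eligible: 0.0045
  risk_concentration: 2.0
  clinical_stage_distribution:
  - 0.163
  - 0.078
  - 0.277
  - 0.482
settings:
  uptake: 0.5
  adherence: 1.0
  n_rounds: 17.0
  cycle_length: 0.25
  horizon: 42.0
  accrual_horizon: 42.0
  wtp: 50000.0
  discount_rate_costs: 0.05
  discount_rate_health: 0.05
  half_cycle_correction: no
costs:
  stage:
    I:
      first_3_months: 8564.0
      rest_of_year1: 1956.0
      year2: 736.0
      second_line: 32085.0
    II:
      first_3_months: 8215.0
      rest_of_year1: 2588.0
      year2: 736.0
      second_line: 32085.0
    III:
      first_3_months: 16606.0
      rest_of_year1: 41502.0
      year2: 13598.0
      second_line: 24795.0
    IV:
      first_3_months: 12529.0
      rest_of_year1: 25442.0
      year2: 2517.0
      second_line: 24795.0
  invitation_letter: 3.0
  gp_consult: 22.0
  ct_scan: 280.0
  diag_screen_detected: 803.0
  diag_clinical: 1093.0
  followup_ct: 280.0
  followup_consult: 88.0
  end_of_life: 7466.0
utilities:
  pre_progression:
  - 0.78
  - 0.78
  - 0.69
  - 0.69
  post_progression:
  - 0.69
  - 0.69
  - 0.69
  - 0.69
  population_utility_by_age:
    age:
    - 18
    - 19
    - 20
    - 21
    - 22
    - 23
    - 24
    - 25
    - 26
    - 27
    - 28
    - 29
    - 30
    - 31
    - 32
    - 33
    - 34
    - 35
    - 36
    - 37
    - 38
    - 39
    - 40
    - 41
    - 42
    - 43
    - 44
    - 45
    - 46
    - 47
    - 48
    - 49
    - 50
    - 51
    - 52
    - 53
    - 54
    - 55
    - 56
    - 57
    - 58
    - 59
    - 60
    - 61
    - 62
    - 63
    - 64
    - 65
    - 66
    - 67
    - 68
    - 69
    - 70
    - 71
    - 72
    - 73
    - 74
    - 75
    - 76
    - 77
    - 78
    - 79
    - 80
    - 81
    - 82
    - 83
    - 84
    - 85
    - 86
    - 87
    - 88
    - 89
    - 90
    - 91
    - 92
    - 93
    - 94
    - 95
    - 96
    - 97
    - 98
    - 99
    - 100
    - 101
    - 102
    - 103
    - 104
    - 105
    - 106
    - 107
    - 108
    utility:
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.89
    - 0.887
    - 0.884
    - 0.881
    - 0.878
    - 0.875
    - 0.872
    - 0.869
    - 0.866
    - 0.863
    - 0.86
    - 0.857
    - 0.854
    - 0.851
    - 0.848
    - 0.845
    - 0.842
    - 0.839
    - 0.836
    - 0.833
    - 0.83
    - 0.827
    - 0.824
    - 0.821
    - 0.818
    - 0.815
    - 0.812
    - 0.809
    - 0.806
    - 0.803
    - 0.8
    - 0.797
    - 0.794
    - 0.791
    - 0.788
    - 0.785
    - 0.782
    - 0.779
    - 0.776
    - 0.773
    - 0.77
    - 0.767
    - 0.764
    - 0.761
    - 0.758
    - 0.755
    - 0.752
    - 0.749
    - 0.746
    - 0.743
    - 0.74
    - 0.737
    - 0.734
    - 0.731
    - 0.728
    - 0.725
    - 0.722
    - 0.719
    - 0.716
survival:
  os_5yr:
  - 0.7863
  - 0.549
  - 0.2924
  - 0.0591
  dpfs_1yr:
  - 0.878
  - 0.878
  - 0.4181
  - 0.4013
  missed_behaves_as: II
background_mortality_multiplier: 1.0
special_flags:
  fp_disutility: 0.0
  smoking_cessation_cost: 0.0
  immunotherapy_uplift: 0.0
distributions:
  settings.uptake:
    kind: beta
    mean: 0.5
    se: 0.1
    group_id: ~
  demography.total_population:
    kind: gamma
    mean: 8978929.0
    se: 1795785.800000000046566
    group_id: ~
  demography.frac_aged_50_74:
    kind: beta
    mean: 0.3222
    se: 0.06444
    group_id: ~
  demography.smoking_rate:
    kind: beta
    mean: 0.2076
    se: 0.04152
    group_id: ~
  epidemiology.annual_incidence_eligible:
    kind: gamma
    mean: 0.0045
    se: 0.0009
    group_id: ~
  epidemiology.clinical_stage_distribution.I:
    kind: dirichlet_group
    mean: 0.163
    se: ~
    group_id: clinical_stage
  costs.stage.I.first_3_months:
    kind: gamma
    mean: 8564.0
    se: 1712.800000000000182
    group_id: ~
  costs.stage.I.rest_of_year1:
    kind: gamma
    mean: 1956.0
    se: 391.200000000000045
    group_id: ~
  costs.stage.I.year2:
    kind: gamma
    mean: 736.0
    se: 147.200000000000017
    group_id: ~
  costs.stage.I.second_line:
    kind: gamma
    mean: 32085.0
    se: 6417.0
    group_id: ~
  utilities.pre_progression.I:
    kind: beta
    mean: 0.78
    se: 0.156
    group_id: ~
  utilities.post_progression.I:
    kind: beta
    mean: 0.69
    se: 0.138
    group_id: ~
  epidemiology.clinical_stage_distribution.II:
    kind: dirichlet_group
    mean: 0.078
    se: ~
    group_id: clinical_stage
  costs.stage.II.first_3_months:
    kind: gamma
    mean: 8215.0
    se: 1643.0
    group_id: ~
  costs.stage.II.rest_of_year1:
    kind: gamma
    mean: 2588.0
    se: 517.600000000000023
    group_id: ~
  costs.stage.II.year2:
    kind: gamma
    mean: 736.0
    se: 147.200000000000017
    group_id: ~
  costs.stage.II.second_line:
    kind: gamma
    mean: 32085.0
    se: 6417.0
    group_id: ~
  utilities.pre_progression.II:
    kind: beta
    mean: 0.78
    se: 0.156
    group_id: ~
  utilities.post_progression.II:
    kind: beta
    mean: 0.69
    se: 0.138
    group_id: ~
  epidemiology.clinical_stage_distribution.III:
    kind: dirichlet_group
    mean: 0.277
    se: ~
    group_id: clinical_stage
  costs.stage.III.first_3_months:
    kind: gamma
    mean: 16606.0
    se: 3321.200000000000273
    group_id: ~
  costs.stage.III.rest_of_year1:
    kind: gamma
    mean: 41502.0
    se: 8300.399999999999636
    group_id: ~
  costs.stage.III.year2:
    kind: gamma
    mean: 13598.0
    se: 2719.600000000000364
    group_id: ~
  costs.stage.III.second_line:
    kind: gamma
    mean: 24795.0
    se: 4959.0
    group_id: ~
  utilities.pre_progression.III:
    kind: beta
    mean: 0.69
    se: 0.138
    group_id: ~
  utilities.post_progression.III:
    kind: beta
    mean: 0.69
    se: 0.138
    group_id: ~
  epidemiology.clinical_stage_distribution.IV:
    kind: dirichlet_group
    mean: 0.482
    se: ~
    group_id: clinical_stage
  costs.stage.IV.first_3_months:
    kind: gamma
    mean: 12529.0
    se: 2505.800000000000182
    group_id: ~
  costs.stage.IV.rest_of_year1:
    kind: gamma
    mean: 25442.0
    se: 5088.400000000000546
    group_id: ~
  costs.stage.IV.year2:
    kind: gamma
    mean: 2517.0
    se: 503.400000000000034
    group_id: ~
  costs.stage.IV.second_line:
    kind: gamma
    mean: 24795.0
    se: 4959.0
    group_id: ~
  utilities.pre_progression.IV:
    kind: beta
    mean: 0.69
    se: 0.138
    group_id: ~
  utilities.post_progression.IV:
    kind: beta
    mean: 0.69
    se: 0.138
    group_id: ~
  costs.invitation_letter:
    kind: gamma
    mean: 3.0
    se: 0.6
    group_id: ~
  costs.gp_consult:
    kind: gamma
    mean: 22.0
    se: 4.4
    group_id: ~
  costs.ct_scan:
    kind: gamma
    mean: 280.0
    se: 56.0
    group_id: ~
  costs.diag_screen_detected:
    kind: gamma
    mean: 803.0
    se: 160.600000000000023
    group_id: ~
  costs.diag_clinical:
    kind: gamma
    mean: 1093.0
    se: 218.600000000000023
    group_id: ~
  costs.followup_ct:
    kind: gamma
    mean: 280.0
    se: 56.0
    group_id: ~
  costs.followup_consult:
    kind: gamma
    mean: 88.0
    se: 17.600000000000001
    group_id: ~
  costs.end_of_life:
    kind: gamma
    mean: 7466.0
    se: 1493.200000000000045
    group_id: ~
  background_mortality_multiplier:
    kind: gamma
    mean: 1.0
    se: 0.2
    group_id: ~

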