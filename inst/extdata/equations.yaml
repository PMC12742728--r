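Ch:
  id: Ch
  name: Chumlea
  sex_specific: yes
  variables:
  - mac_cm
  - cc_cm
  - sst_mm
  - kh_cm
  coefficients:
    male:
      mac_cm: 1.73
      cc_cm: 0.98
      sst_mm: 0.37
      kh_cm: 1.16
    female:
      mac_cm: 0.98
      cc_cm: 1.27
      sst_mm: 0.4
      kh_cm: 0.87
  intercept:
    male: -81.689999999999998
    female: -62.350000000000001
  provenance_r2:
    male: 0.9
    female: 0.85
R1:
  id: R1
  name: Rabito 1
  sex_specific: no
  variables:
  - mac_cm
  - ac_cm
  - cc_cm
  - sst_mm
  coefficients:
    mac_cm: 0.503
    ac_cm: 0.5632
    cc_cm: 1.318
    sst_mm: 0.0339
  intercept:
  - -43.155999999999999
  provenance_r2:
  - 0.93
R2:
  id: R2
  name: Rabito 2
  sex_specific: no
  variables:
  - mac_cm
  - ac_cm
  - cc_cm
  coefficients:
    mac_cm: 0.4808
    ac_cm: 0.5646
    cc_cm: 1.316
  intercept:
  - -42.244999999999997
  provenance_r2:
  - 0.93
R3:
  id: R3
  name: Rabito 3
  sex_specific: no
  variables:
  - mac_cm
  - ac_cm
  - cc_cm
  coefficients:
    mac_cm: 0.5759
    ac_cm: 0.5263
    cc_cm: 1.2452
    sex_code: -4.8689
  intercept:
  - -32.924100000000003
  provenance_r2:
  - 0.94
Cr:
  id: Cr
  name: Crandall
  sex_specific: yes
  variables:
  - mac_cm
  - height_cm
  coefficients:
    male:
      mac_cm: 3.29
      height_cm: 0.43
    female:
      mac_cm: 2.15
      height_cm: 0.54
  intercept:
    male: -93.200000000000003
    female: -64.599999999999994
  provenance_r2:
    male: 0.59
    female: 0.55
L:
  id: L
  name: Lorenz
  sex_specific: yes
  variables:
  - height_cm
  - ac_cm
  - hc_cm
  coefficients:
    male:
      height_cm: 0.60035
      ac_cm: 0.785
      hc_cm: 0.392
    female:
      height_cm: 0.4053
      ac_cm: 0.325
      hc_cm: 0.836
  intercept:
    male: -137.431999999999988
    female: -110.924000000000007
  provenance_r2:
    male: 0.85
    female: 0.82
KK:
  id: KK
  name: Kokong
  sex_specific: no
  variables: height_cm
  coefficients:
    height_cm: 1.0
  intercept:
  - -100.0
  provenance_r2:
  - 1.0
J:
  id: J
  name: Jung
  sex_specific: yes
  variables:
  - kh_cm
  - mac_cm
  - age_years
  coefficients:
    male:
      kh_cm: 0.928
      mac_cm: 2.508
      age_years: -0.144
    female:
      kh_cm: 0.826
      mac_cm: 2.116
      age_years: -0.133
  intercept:
    male: -42.542999999999999
    female: -31.486000000000001
  provenance_r2:
    male: 0.81
    female: 0.133
C:
  id: C
  name: Cattermole
  sex_specific: no
  variables: mac_cm
  coefficients:
    mac_cm: 4.0
  intercept:
  - -50.0
  provenance_r2:
  - .na.real
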