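# Yearly atmospheric CO2 curve coefficients per SSP scenario.
# Each curve is sum over terms of coef * (year - center)^degree.
# The shifted-polynomial terms follow the published empirical fits; the
# leading constant of each scenario anchors the curve at 340 ppm in 1981
# (reconstruction: see the methods vignette). Edit freely; every edited
# set must still pass build_trajectory() validation.
SSP126:
  year_range: [1981, 2070]
  terms:
    - {coef: 170.0566469, center: 0, degree: 0}
    - {coef: 4.5948, center: 1961, degree: 1}
    - {coef: -0.023987, center: 1977, degree: 2}
    - {coef: -0.00024959, center: 2054, degree: 3}
    - {coef: -6.5721e-07, center: 2054, degree: 4}
SSP245:
  year_range: [1981, 2070]
  terms:
    - {coef: 67.00796277, center: 0, degree: 0}
    - {coef: 0.028057, center: 1900, degree: 2}
    - {coef: 0.00026827, center: 1960, degree: 3}
    - {coef: -9.2751e-07, center: 1910, degree: 4}
    - {coef: -2.2448, center: 2030, degree: 1}
SSP370:
  year_range: [1981, 2070]
  terms:
    - {coef: 157.1673009, center: 0, degree: 0}
    - {coef: 4.752e-05, center: 143.55, degree: 2}
    - {coef: 0.0001037, center: 1908, degree: 3}
    - {coef: -5.9113e-08, center: 1849, degree: 4}
SSP585:
  year_range: [1981, 2070]
  terms:
    - {coef: -659.1687712, center: 0, degree: 0}
    - {coef: 0.00024712, center: -15, degree: 2}
    - {coef: 1.9299e-05, center: 1937, degree: 3}
    - {coef: 5.1137e-07, center: 1910, degree: 4}
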