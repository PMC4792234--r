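# Synthetic size-exclusion calibration standards (not measured data).
# Five classical gel-filtration standards placed on a log-linear
# log10(mass) vs Ve/Vo curve (intercept 8.0, slope -2.2, void volume
# 8.0 mL, Superose-12-scale column) with ~0.4% jitter on the elution
# volumes. standard: thyroglobulin, gamma-globulin, ovalbumin,
# myoglobin, vitamin B12.
Ve_mL	mass_Da
7.951	669000
10.164	158000
12.223	44000
13.742	17000
17.737	1350
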