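# Synthetic stand-in risk-equation set with plausible magnitudes.
# These are NOT published UKPDS 82 estimates: absolute outcome
# magnitudes produced with this file are illustrative only.
# Format: one block per event; form in {logistic, cloglog, weibull,
# gompertz}; weibull requires a shape line; death block mandatory.

event ihd
form logistic
recurrent no
coef intercept -8.800
coef hba1c 0.250
coef age 0.035
coef sbp 0.005
coef female -0.200

event mi
form cloglog
recurrent yes
coef intercept -9.50
coef hba1c 0.30
coef age 0.04
coef smoker 0.40
coef hist_mi 0.80

event chf
form cloglog
recurrent no
coef intercept -10.50
coef age 0.07
coef bmi 0.04

event stroke
form cloglog
recurrent yes
coef intercept -10.000
coef age 0.055
coef sbp 0.012
coef hba1c 0.120

event amputation
form logistic
recurrent no
coef intercept -9.50
coef hba1c 0.35
coef duration 0.03
coef hist_pvd 1.00

event blindness
form weibull
recurrent no
shape 1.4
coef intercept -8.0
coef hba1c 0.2
coef hist_retinopathy 0.7

event renal
form logistic
recurrent no
coef intercept -4.20
coef egfr -0.03
coef duration 0.04
coef hist_microalbuminuria 1.20
coef hist_renal 1.00

event ulcer
form logistic
recurrent yes
coef intercept -7.80
coef hba1c 0.15
coef hist_pvd 0.80
coef duration 0.02

event death
form gompertz
recurrent no
coef intercept -9.800
coef age 0.088
coef hba1c 0.060
coef hist_mi 0.300
coef prior_mi 0.400
coef prior_stroke 0.400
coef prior_chf 0.500
coef prior_renal 0.900

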