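# Marginal moments and observed support of the seven study variables on the
# 14-country x 23-year European panel (levels, before log rescaling).
# HEALTH is recorded as mean 6.4149, sd 1.0745: the published summary row is
# internally inconsistent (a decimal slip), and only these magnitudes are
# consistent with its coefficient of variation 16.75 and support 3.7-8.9.
variable,mean,sd,min,max
LEAB,79.74,1.845,75.3,83.5
LEDU,62.493,14.102,19.3,82.3
ENVIRO,0.7792,0.3439,0.2,1.7
SOPRO,18.109,3.685,9.5,25.5
HEALTH,6.4149,1.0745,3.7,8.9
KOF,84.089,4.458,68.112,91.313
GNI,29.872,10.954,9.151,65.663
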