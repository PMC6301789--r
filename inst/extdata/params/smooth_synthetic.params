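# Dinucleotide parameter set "smooth_synthetic" (alternative).
#
# Same axis conventions, twists and stiffness table as wedge_synthetic, but
# with all wedge (tilt/roll) magnitudes halved. Shipped to expose the
# sensitivity of pinning predictions to the choice of dinucleotide geometry
# set: predicted intrinsic curvature, and hence peak contrast in the
# plectoneme density, is systematically weaker with this set. Synthetic
# composite values; see wedge_synthetic.params for provenance notes.
#
# columns: step tilt(deg) roll(deg) twist(deg) var_tilt(rad^2) var_roll(rad^2) cov_tilt_roll(rad^2)
name smooth_synthetic
rise 0.334
bulk_persistence_length 50
AA  -0.3  -1.8  35.6  0.0050  0.0050  0
AC  -0.05  0.15 34.4  0.0060  0.0062  0
AG   0.5   1.3  27.7  0.0065  0.0070  0
AT   0.0  -0.9  31.5  0.0055  0.0055  0
CA   0.15  1.9  34.5  0.0067  0.0090  0
CC  -0.05  1.0  33.7  0.0060  0.0060  0
CG   0.0   1.6  29.8  0.0067  0.0090  0
CT  -0.5   1.3  27.7  0.0065  0.0070  0
GA   0.45  0.6  36.9  0.0065  0.0070  0
GC   0.0   0.3  40.0  0.0067  0.0080  0
GG   0.05  1.0  33.7  0.0060  0.0060  0
GT   0.05  0.15 34.4  0.0060  0.0062  0
TA   0.0   2.3  36.0  0.0067  0.0100  0
TC  -0.45  0.6  36.9  0.0065  0.0070  0
TG  -0.15  1.9  34.5  0.0067  0.0090  0
TT   0.3  -1.8  35.6  0.0050  0.0050  0
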