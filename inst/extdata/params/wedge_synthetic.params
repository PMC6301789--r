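# Dinucleotide geometry + stiffness parameter set "wedge_synthetic" (default).
#
# PROVENANCE / CONVENTIONS
# This is a SYNTHETIC composite wedge-style set, assembled in the spirit of the
# classical dinucleotide wedge/crystallographic parameterizations of intrinsic
# DNA shape. It is NOT a transcription of any single published table; the
# values were constructed once, before any model evaluation, to reproduce
# well-established macroscopic benchmarks of sequence-dependent DNA shape:
#   * mean twist ~ 33.9 deg/step (helical repeat ~ 10.6 bp);
#   * phased A-tract macrocurvature of roughly 18-24 deg per helical turn
#     (A-tract steps carry negative roll relative to the generic background,
#     pyrimidine-purine steps carry large positive roll);
#   * a "static" persistence length from wedge dispersion of several hundred
#     nm, i.e. wedge heterogeneity well below the thermal bending scale;
#   * strand-complement symmetry: roll(s) = roll(revcomp s),
#     tilt(s) = -tilt(revcomp s), twist(s) = twist(revcomp s).
#
# AXIS CONVENTIONS
# Right-handed material frame (t, n, b) per base pair; per step the frame is
# updated by twist about t, then roll about n, then tilt about b (in that
# order). Positive roll deflects the tangent toward -b; positive tilt toward
# +n. Angles are degrees in this file and converted to radians exactly once at
# load.
#
# STIFFNESS
# var_tilt / var_roll are per-step thermal variances (radians^2) of the tilt
# and roll angles; cov_tilt_roll is their covariance. The table average of the
# per-plane variance is ~ 0.00662 rad^2 ~= rise / bulk_persistence_length
# (0.334 nm / 50 nm), so the sequence-averaged directional persistence length
# of random DNA is ~ 50 nm. Pyrimidine-purine steps are softest; A-tract steps
# are stiffest and isotropic.
#
# columns: step tilt(deg) roll(deg) twist(deg) var_tilt(rad^2) var_roll(rad^2) cov_tilt_roll(rad^2)
name wedge_synthetic
rise 0.334
bulk_persistence_length 50
AA  -0.6  -3.6  35.6  0.0050  0.0050  0
AC  -0.1   0.3  34.4  0.0060  0.0062  0
AG   1.0   2.6  27.7  0.0065  0.0070  0
AT   0.0  -1.8  31.5  0.0055  0.0055  0
CA   0.3   3.8  34.5  0.0067  0.0090  0
CC  -0.1   2.0  33.7  0.0060  0.0060  0
CG   0.0   3.2  29.8  0.0067  0.0090  0
CT  -1.0   2.6  27.7  0.0065  0.0070  0
GA   0.9   1.2  36.9  0.0065  0.0070  0
GC   0.0   0.6  40.0  0.0067  0.0080  0
GG   0.1   2.0  33.7  0.0060  0.0060  0
GT   0.1   0.3  34.4  0.0060  0.0062  0
TA   0.0   4.6  36.0  0.0067  0.0100  0
TC  -0.9   1.2  36.9  0.0065  0.0070  0
TG  -0.3   3.8  34.5  0.0067  0.0090  0
TT   0.6  -3.6  35.6  0.0050  0.0050  0
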