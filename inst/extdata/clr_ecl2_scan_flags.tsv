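# Alanine-scan significance/direction table for the receptor loop segment
# 271-294 (alanines mutated to leucine), both ligands, plus the L290AL291A
# double mutant with its reported pEC50 means. Encoding notes:
#  - 'significant' and the SIGN of 'pec50_shift' follow the published scan
#    outcome; residues whose identity is not given in the source tables are
#    labelled with the placeholder letter X.
#  - shift MAGNITUDES are placeholders except where means were printed
#    (L290A ~8-fold, L291A ~4-fold, L290AL291A with pEC50 7.93 vs WT 10.6):
#    large significant losses (>10-fold) are encoded as -1.2, small
#    significant losses as -0.5, the N281A potency gain as +0.3.
#  - key-residue derivation uses only 'significant' and the shift sign.
#mutant	ligand	significant	pec50_shift	pec50_mean	wt_pec50_mean	note
A271L	CGRP	no	0	NA	NA
X272A	CGRP	no	0	NA	NA
A273L	CGRP	yes	-0.5	NA	NA	small_loss
R274A	CGRP	yes	-1.2	NA	NA	large_loss
X275A	CGRP	no	0	NA	NA
X276A	CGRP	no	0	NA	NA
Y277A	CGRP	yes	-0.5	NA	NA	small_loss
Y278A	CGRP	yes	-1.2	NA	NA	large_loss
X279A	CGRP	no	0	NA	NA
D280A	CGRP	yes	-1.2	NA	NA	large_loss
N281A	CGRP	yes	0.3	NA	NA	potency_gain
C282A	CGRP	yes	-1.2	NA	NA	large_loss
W283A	CGRP	yes	-1.2	NA	NA	large_loss
I284A	CGRP	yes	-1.2	NA	NA	large_loss
S285A	CGRP	yes	-0.5	NA	NA	small_loss
X286A	CGRP	no	0	NA	NA
D287A	CGRP	yes	-0.5	NA	NA	small_loss
T288A	CGRP	yes	-1.2	NA	NA	large_loss
X289A	CGRP	no	0	NA	NA
L290A	CGRP	yes	-0.90	NA	NA	small_loss_8fold
L291A	CGRP	yes	-0.60	NA	NA	small_loss_4fold
Y292A	CGRP	no	0	NA	NA	emax_effect_only
X293A	CGRP	no	0	NA	NA
I294A	CGRP	no	0	NA	NA	emax_effect_only
L290AL291A	CGRP	yes	-2.67	7.93	10.6	double_mutant_printed_means
A271L	AM	no	0	NA	NA
X272A	AM	no	0	NA	NA
A273L	AM	yes	-1	NA	NA
R274A	AM	yes	-1	NA	NA
X275A	AM	no	0	NA	NA
X276A	AM	no	0	NA	NA
Y277A	AM	no	0	NA	NA
Y278A	AM	no	0	NA	NA
X279A	AM	no	0	NA	NA
D280A	AM	yes	-1	NA	NA
N281A	AM	no	0	NA	NA
C282A	AM	no	0	NA	NA
W283A	AM	yes	-1	NA	NA
I284A	AM	yes	-1	NA	NA
S285A	AM	yes	-1	NA	NA
X286A	AM	no	0	NA	NA
D287A	AM	no	0	NA	NA
T288A	AM	yes	-1	NA	NA
X289A	AM	no	0	NA	NA
L290A	AM	no	0	NA	NA
L291A	AM	no	0	NA	NA
Y292A	AM	no	0	NA	NA
X293A	AM	no	0	NA	NA
I294A	AM	no	0	NA	NA
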