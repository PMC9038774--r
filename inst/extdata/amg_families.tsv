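pfam_family	amg_category
GH13	C
GH16	C
GH23	C
GH25	C
GH5	C
GT2	C
GT4	C
GT25	C
CBM50	C
CBM13	C
Glyco_hydro_19	C
CE4	C
AA3	C
norD	N
norQ	N
NirD	N
NapB	N
Amidase	N
GdhA	N
PhoD	P
PhoX	P
phnP	P
PhoH	P
cysD	S
cysH	S
CysC	S
Sulfatase	S
TauD	S
ALDH	pesticide
Aldedh	pesticide
HAD	pesticide
HAD_2	pesticide
Hydrolase	pesticide
DhlB	pesticide
LinB	pesticide
AtzA	pesticide
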