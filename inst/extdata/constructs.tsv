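name	sequence	notes
cMyc	TGG CGA CGG CAG CGA GGC GGG T GGG GA GGG T GGG/3'Cy3/	oncogenic promoter GQ; parallel-only in 100 mM KCl
133	TGG CGA CGG CAG CGA GGC GGG T GGG TTT GGG TTT GGG/3'Cy3/	loop lengths 1,3,3
144	TGG CGA CGG CAG CGA GGC GGG T GGG TTTT GGG TTTT GGG/3'Cy3/	loop lengths 1,4,4
155	TGG CGA CGG CAG CGA GGC GGG T GGG TTTTT GGG TTTTT GGG/3'Cy3/	loop lengths 1,5,5
177	TGG CGA CGG CAG CGA GGC GGG T GGG TTTTTTT GGG TTTTTTT GGG/3'Cy3/	loop lengths 1,7,7
199	TGG CGA CGG CAG CGA GGC GGG T GGG TTTTTTTTT GGG TTTTTTTTT GGG/3'Cy3/	loop lengths 1,9,9; exceeds the N1-7 motif bound
233	TGG CGA CGG CAG CGA GGC GGG TT GGG TTT GGG TTT GGG/3'Cy3/	loop lengths 2,3,3
333	TGG CGA CGG CAG CGA GGC GGG TTT GGG TTT GGG TTT GGG/3'Cy3/	loop lengths 3,3,3; same sequence as TTT
433	TGG CGA CGG CAG CGA GGC GGG TTTT GGG TTT GGG TTT GGG/3'Cy3/	loop lengths 4,3,3
533	TGG CGA CGG CAG CGA GGC GGG TTTTT GGG TTT GGG TTT GGG/3'Cy3/	loop lengths 5,3,3
TTA	TGG CGA CGG CAG CGA GGC GGG TTA GGG TTA GGG TTA GGG/3'Cy3/	human telomere repeat loops
TAA	TGG CGA CGG CAG CGA GGC GGG TAA GGG TAA GGG TAA GGG/3'Cy3/	loop sequence variant
AAA	TGG CGA CGG CAG CGA GGC GGG AAA GGG AAA GGG AAA GGG/3'Cy3/	loop sequence variant; mostly unfolded
T25	TGG CGA CGG CAG CGA GGC (T)25/3'Cy3/	non-GQ control; 25 nt deoxy-thymidine overhang
Amino18nt	GCC TCG C/iamino/TG CCG TCG CCA/3'Bio/	stem complement; annealed to all 3' Cy3 sequences above
313	TGG CGA CGG CAG CGA GGC GGG TTT GGG T GGG TTT GGG	single-nt loop in middle position
331	TGG CGA CGG CAG CGA GGC GGG TTT GGG TTT GGG T GGG	single-nt loop in third position
515	TGG CGA CGG CAG CGA GGC GGG TTTTT GGG T GGG TTTTT GGG	single-nt loop in middle position
551	TGG CGA CGG CAG CGA GGC GGG TTTTT GGG TTTTT GGG T GGG	single-nt loop in third position
717	TGG CGA CGG CAG CGA GGC GGG TTTTTTT GGG T GGG TTTTTTT GGG	single-nt loop in middle position
771	TGG CGA CGG CAG CGA GGC GGG TTTTTTT GGG TTTTTTT GGG T GGG	single-nt loop in third position
919	TGG CGA CGG CAG CGA GGC GGG TTTTTTTTT GGG T GGG TTTTTTTTT GGG	single-nt loop in middle position
991	TGG CGA CGG CAG CGA GGC GGG TTTTTTTTT GGG TTTTTTTTT GGG T GGG	single-nt loop in third position
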