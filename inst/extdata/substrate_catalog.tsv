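# cazyprofiler substrate catalog v1
# Curated mapping from CAZy families, EC numbers, sulfatase S1 subfamilies and
# mannitol-pathway gene symbols to macroalgal dietary substrates and
# molecular-weight classes. Reconstructed from published enzyme-substrate
# associations for brown/red algal polysaccharides; edit and re-version as
# curation evolves. 'dedicated' means unambiguous for a single substrate.
# weight_class HMW = endo-acting / polymer-cleaving, LMW = exo-acting /
# oligomer-consuming, NA = not applicable (binding modules, sulfatases,
# pathway genes).
key	key_type	substrates	weight_class	dedicated	enzyme_label
PL6	family	alginate	HMW	TRUE	guluronate-specific alginate lyase
PL34	family	alginate	HMW	TRUE	mannuronate-specific alginate lyase
PL38	family	alginate	HMW	TRUE	alginate lyase
PL17	family	alginate	LMW	TRUE	oligo-alginate lyase
GH16	family	laminarin,agarose	HMW	FALSE	endo-1,3(4)-beta-glucanase / beta-agarase
GH149	family	laminarin	HMW	TRUE	beta-1,3-glucan phosphorylase
GH30	family	laminarin,FCSP	HMW	FALSE	glucan endo-1,6-beta-glucosidase / fucosidase
GH3	family	laminarin	LMW	FALSE	beta-glucosidase
GH1	family	laminarin	LMW	FALSE	beta-glucosidase
GH29	family	FCSP	HMW	TRUE	alpha-L-fucosidase
GH141	family	FCSP	HMW	TRUE	alpha-L-fucosidase
GH151	family	FCSP	HMW	TRUE	alpha-L-fucosidase
GH150	family	carrageenan	HMW	TRUE	lambda-carrageenase
GH86	family	agarose	HMW	TRUE	beta-agarase
GH50	family	agarose	HMW	TRUE	beta-agarase
GH13	family	starch	HMW	TRUE	alpha-amylase / pullulanase
GH57	family	starch	HMW	TRUE	alpha-amylase
GH77	family	starch	HMW	TRUE	4-alpha-glucanotransferase
GH133	family	starch	LMW	TRUE	amylo-alpha-1,6-glucosidase
GH31	family	starch	LMW	TRUE	alpha-glucosidase
GH2	family	galactan	LMW	TRUE	beta-galactosidase
GH42	family	galactan	LMW	TRUE	beta-galactosidase
GH36	family	galactan	LMW	TRUE	alpha-galactosidase
GH110	family	galactan	LMW	TRUE	alpha-galactosidase
CE1	family		NA	FALSE	carbohydrate esterase
CE6	family		NA	FALSE	acetyl xylan esterase
CBM32	family		NA	FALSE	galactose-binding module
CBM48	family		NA	FALSE	glycogen-binding module
GT2	family		NA	FALSE	glycosyltransferase
AA3	family		NA	FALSE	auxiliary redox enzyme
S1_7	s1	carrageenan,sulfate_removal	NA	FALSE	kappa/iota-carrageenan G4S sulfatase
S1_19	s1	carrageenan,sulfate_removal	NA	FALSE	kappa/iota-carrageenan G4S sulfatase
S1_8	s1	carrageenan,sulfate_removal	NA	FALSE	lambda-carrageenan G2S sulfatase
S1_15	s1	FCSP,sulfate_removal	NA	FALSE	fucoidan C2/C3 sulfatase
S1_16	s1	FCSP,sulfate_removal	NA	FALSE	fucoidan sulfatase
S1_17	s1	FCSP,carrageenan,sulfate_removal	NA	FALSE	fucoidan C4 / iota-carrageenan C2 sulfatase
S1_25	s1	FCSP,sulfate_removal	NA	FALSE	fucose C3 exo-sulfatase
m2dh	gene	mannitol	NA	TRUE	mannitol 2-dehydrogenase
fructokinase	gene	mannitol	NA	TRUE	fructokinase
pts_mtl	gene	mannitol	NA	TRUE	mannitol PTS component
m1pdh	gene	mannitol	NA	TRUE	mannitol-1-phosphate 5-dehydrogenase
4.2.2.25	ec	alginate	HMW	TRUE	guluronate-specific alginate lyase
4.2.2.3	ec	alginate	HMW	TRUE	poly(beta-D-mannuronate) lyase
4.2.2.26	ec	alginate	LMW	TRUE	oligo-alginate lyase
3.2.1.75	ec	laminarin	HMW	TRUE	glucan endo-1,6-beta-glucosidase
3.2.1.39	ec	laminarin	HMW	TRUE	glucan endo-1,3-beta-D-glucosidase
3.2.1.6	ec	laminarin	HMW	TRUE	endo-1,3(4)-beta-glucanase
3.2.1.21	ec	laminarin	LMW	TRUE	beta-glucosidase
3.2.1.51	ec	FCSP	HMW	TRUE	alpha-L-fucosidase
3.2.1.83	ec	carrageenan	HMW	TRUE	kappa-carrageenase
3.2.1.157	ec	carrageenan	HMW	TRUE	iota-carrageenase
3.2.1.162	ec	carrageenan	HMW	TRUE	lambda-carrageenase
3.2.1.81	ec	agarose	HMW	TRUE	beta-agarase
3.2.1.23	ec	galactan	LMW	TRUE	beta-galactosidase
3.2.1.22	ec	galactan	LMW	TRUE	alpha-galactosidase
3.2.1.1	ec	starch	HMW	TRUE	alpha-amylase
3.2.1.41	ec	starch	HMW	TRUE	pullulanase
3.2.1.68	ec	starch	HMW	TRUE	isoamylase
3.2.1.135	ec	starch	HMW	TRUE	neopullulanase
3.2.1.10	ec	starch	LMW	TRUE	oligo-1,6-glucosidase
3.2.1.20	ec	starch	LMW	TRUE	alpha-1,4-glucosidase
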