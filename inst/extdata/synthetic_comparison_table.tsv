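gene	fc.YR36.WR36	q.YR36.WR36	sig.YR36.WR36	ish.YR36.WR36	fc.YR52.WR52	q.YR52.WR52	sig.YR52.WR52	ish.YR52.WR52	fc.WR52.WR36	q.WR52.WR36	sig.WR52.WR36	ish.WR52.WR36	fc.YR52.YR36	q.YR52.YR36	sig.YR52.YR36	ish.YR52.YR36
gene00001	-2.75282834039864	5.71640625966895e-05	TRUE	-1	-2.75282834039864	5.71640625966895e-05	TRUE	-1	1.63375281928305	0.0234345076831019	FALSE	0	1.63375281928305	0.0234345076831019	FALSE	0
gene00002	3.28890505068126	3.37481138227556e-07	TRUE	1	8.30009069151802	7.19818187992214e-11	TRUE	1	1.21404220407595	0.134622212073165	FALSE	0	3.06383438922128	7.87037298515872e-07	TRUE	1
gene00003	-2.53327562122618	3.15393328201485e-06	TRUE	-1	-2.53327562122618	3.15393328201485e-06	TRUE	-1	1.60246354376009	0.00459340634332618	FALSE	-1	1.60246354376009	0.00689010951498926	FALSE	0
gene00004	-3.02936415493643	1.92192022201745e-06	TRUE	-1	-3.02936415493643	1.92192022201745e-06	TRUE	-1	1.32159032119206	0.0693997377305445	FALSE	0	1.32159032119206	0.0693997377305445	FALSE	0
gene00005	2.5171414406578	7.36814895238243e-06	TRUE	1	2.5171414406578	7.36814895238243e-06	TRUE	1	1.51588852994468	0.0132240632030095	FALSE	0	1.51588852994468	0.0165300790037619	FALSE	0
gene00006	-2.03650239873058	0.00102904041531886	TRUE	-1	-2.03650239873058	0.00102904041531886	TRUE	-1	1.54530639746979	0.0298724726017337	FALSE	0	1.54530639746979	0.0298724726017337	FALSE	0
gene00007	-1.00103948731558	0.993957926372476	FALSE	0	-1.2070772570442	0.649388158328415	FALSE	0	2.36392563609526	0.000111602781582817	TRUE	1	1.96042373675698	0.0234345076831019	FALSE	0
gene00008	-1.07092934521892	0.672515285722645	FALSE	0	-1.07092934521892	0.747239206358494	FALSE	0	1.50100845635849	0.00845156659982401	FALSE	0	1.50100845635849	0.011268755466432	FALSE	0
gene00009	1.01130784664706	0.993957926372476	FALSE	0	1.01130784664706	0.925416931367648	FALSE	0	1.16297684092991	0.219846662547008	FALSE	0	1.16297684092991	0.239832722778554	FALSE	0
gene00010	1.2618358632589	0.171694941699819	FALSE	0	1.48458743572978	0.182155052709684	FALSE	0	1.33672414959966	0.0671171934911055	FALSE	0	1.57269573271358	0.0809547473884361	FALSE	0
gene00011	1.15730332308155	0.430840711104391	FALSE	0	1.04440844280467	0.925416931367648	FALSE	0	1.27401370111557	0.104087912604533	FALSE	0	1.1497337294003	0.55233244817591	FALSE	-1
gene00012	1.07947265596963	0.558972377713762	FALSE	0	1.04688701778843	0.925416931367648	FALSE	0	1.50724179698086	0.00242742440638612	FALSE	0	1.46174325139344	0.0454638517379733	FALSE	0
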