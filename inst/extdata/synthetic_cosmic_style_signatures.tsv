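Type	SynthSigA	SynthSigB	Annotation
A[C>A]A	0.00133710029959887	0.001227878599877212	synthetic
A[C>A]C	0.02168037499349589	0.0017653082998234692	fixture
A[C>A]G	0.002218773799334368	1.0826279998917372e-4	synthetic
A[C>A]T	2.0689599993793118e-5	0.0012144087998785592	fixture
C[C>A]A	0.00417523199874743	6.989999999300999e-8	synthetic
C[C>A]C	1.449999999565e-8	0.014627321098537267	fixture
C[C>A]G	1.9519999994144e-7	0.0013839390998616062	synthetic
C[C>A]T	9.158035997252589e-4	0.006637007399336299	fixture
G[C>A]A	2.1285919993614222e-4	1.6077959998392203e-4	synthetic
G[C>A]C	6.837113997948865e-4	0.0032121028996787895	fixture
G[C>A]G	0.0016214886995135533	1.6543959998345604e-4	synthetic
G[C>A]T	7.08536699787439e-4	2.702816999729718e-4	fixture
T[C>A]A	0.010361717196891485	0.0020950246997904973	synthetic
T[C>A]C	0.011429541996571136	0.0010023746998997624	fixture
T[C>A]G	0.004180962998745711	0.025533329197446667	synthetic
T[C>A]T	0.021764609993470616	0.017499045898250094	fixture
A[C>G]A	0.01058342889682497	5.188238999481176e-4	synthetic
A[C>G]C	0.00443293489867012	0.012850811598714918	fixture
A[C>G]G	7.311039997806687e-5	3.8936249996106374e-4	synthetic
A[C>G]T	6.981095997905671e-4	0.004672416899532759	fixture
C[C>G]A	0.013209720596037084	0.012640709598735929	synthetic
C[C>G]C	7.75003699767499e-4	0.021667906097833207	fixture
C[C>G]G	1.1300399996609879e-5	0.03823338369617666	synthetic
C[C>G]T	4.147796998755661e-4	1.0053999998994599e-6	fixture
G[C>G]A	9.970238997008929e-4	0.045916132895408385	synthetic
G[C>G]C	0.008516382197445086	5.228384999477162e-4	fixture
G[C>G]G	0.02507724369247683	0.015242626298475736	synthetic
G[C>G]T	1.1177489996646752e-4	0.0023375741997662424	fixture
T[C>G]A	2.02549999939235e-6	0.03940171339605983	synthetic
T[C>G]C	0.0012058705996382387	0.00143539819985646	fixture
T[C>G]G	0	0.07601840479239816	synthetic
T[C>G]T	0.07330040757800989	4.2596399995740357e-4	fixture
A[C>T]A	0.013647414895905775	6.49999999935e-8	synthetic
A[C>T]C	0.00491646739852506	0.004480417199551958	fixture
A[C>T]G	3.8779999988366e-7	2.3949859997605014e-4	synthetic
A[C>T]T	0.0037275783988817267	0.005334311699466569	fixture
C[C>T]A	0	1.7593119998240688e-4	synthetic
C[C>T]C	5.04229999848731e-6	0.01586947929841305	fixture
C[C>T]G	0.059752942582074114	0.028371073897162893	synthetic
C[C>T]T	1.473509999557947e-5	0.026954766297304523	fixture
G[C>T]A	1.4193699995741888e-5	0.020880533197911947	synthetic
G[C>T]C	7.750357997674893e-4	0.003828889899617111	fixture
G[C>T]G	8.29129999751261e-6	0.06096668339390333	synthetic
G[C>T]T	0.021465844893560244	7.4679999992532e-7	fixture
T[C>T]A	0.003260722299021783	0.0015865642998413435	synthetic
T[C>T]C	0	0.0015737593998426242	fixture
T[C>T]G	0.07562051627731384	2.2069599997793038e-5	synthetic
T[C>T]T	0.0032808986990157307	0.05679270439432073	fixture
A[T>A]A	1.0528349996841494e-4	2.878539999712146e-5	synthetic
A[T>A]C	7.691909997692427e-4	0.05499136269450086	fixture
A[T>A]G	0.019598455294120465	0.0014828381998517163	synthetic
A[T>A]T	2.1996099993401168e-4	3.7068969996293104e-4	fixture
C[T>A]A	0.02585269999224419	7.415525999258447e-4	synthetic
C[T>A]C	1.947319999415804e-5	0.001500038499849996	fixture
C[T>A]G	7.139241997858227e-4	3.370358999662964e-4	synthetic
C[T>A]T	0.0013311015996006696	0.01627262389837274	fixture
G[T>A]A	0.02491542089252537	3.6920449996307955e-4	synthetic
G[T>A]C	0.0062316386981305085	3.06289999969371e-6	fixture
G[T>A]G	4.40119999867964e-6	0.005549713699445029	synthetic
G[T>A]T	0.009203276297239018	4.948187999505181e-4	fixture
T[T>A]A	0.001237376999628787	1.28239999987176e-6	synthetic
T[T>A]C	2.50909999924727e-5	9.79059999902094e-6	fixture
T[T>A]G	0.0029987680991003696	0.007435219199256478	synthetic
T[T>A]T	0.001089815799673055	0.003925168399607483	fixture
A[T>C]A	2.414789999275563e-5	0.020356340097964363	synthetic
A[T>C]C	0.007036177597889146	1.678489999832151e-5	fixture
A[T>C]G	1.37229999958831e-6	0.0011894916998810509	synthetic
A[T>C]T	0.05505880258348236	1.8654119998134586e-4	fixture
C[T>C]A	9.898279997030515e-5	2.308109999769189e-5	synthetic
C[T>C]C	1.0048099996985569e-5	0.03395303219660469	fixture
C[T>C]G	0.0011193121996642063	0.0013687557998631244	synthetic
C[T>C]T	9.99239999700228e-5	0.006484959799351504	fixture
G[T>C]A	0.017729627994681113	0.015499654198450036	synthetic
G[T>C]C	0.01977436259406769	0.0029905847997009414	fixture
G[T>C]G	0.018545434394436372	0.032588468796741155	synthetic
G[T>C]T	0.04840455278547863	9.260746999073925e-4	fixture
T[T>C]A	0.02492576199252227	7.958779999204122e-5	synthetic
T[T>C]C	0.007220211497833937	3.2043699996795626e-5	fixture
T[T>C]G	5.9486499982154046e-5	9.179999999082e-7	synthetic
T[T>C]T	0.031210582490636823	0.06758890989324111	fixture
A[T>G]A	2.002489999399253e-5	0.001562349799843765	synthetic
A[T>G]C	0	0.007231133999276887	fixture
A[T>G]G	0	0.03166557889683344	synthetic
A[T>G]T	9.42509999717247e-6	0.0012129946998787006	fixture
C[T>G]A	0.09152780087254166	0.007148207299285179	synthetic
C[T>G]C	1.5020779995493765e-4	1.920069999807993e-4	fixture
C[T>G]G	0.016978320994906506	6.18229999938177e-6	synthetic
C[T>G]T	2.74293099917712e-4	0.008855816999114419	fixture
G[T>G]A	0.09669245817099226	0.0017183036998281696	synthetic
G[T>G]C	0.047846465985646056	1.169390999883061e-4	fixture
G[T>G]G	4.4803239986559025e-4	1.3429999998657e-7	synthetic
G[T>G]T	2.408903999277329e-4	2.504929999749507e-5	fixture
T[T>G]A	0.012277751796316674	0.0015922433998407756	synthetic
T[T>G]C	2.3876799992836962e-5	0.07730107989226989	fixture
T[T>G]G	2.31189999930643e-5	1.267359999873264e-5	synthetic
T[T>G]T	6.418659998074402e-4	0.008305749199169425	fixture
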