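class	smoking	clock
A[C>A]A	0.029666	0.003085
A[C>A]C	0.004851	0.002195
A[C>A]G	0.168921	0.002458
A[C>A]T	0.025549	0.006248
C[C>A]A	0.011943	0.001031
C[C>A]C	0.028361	0.001488
C[C>A]G	0.081016	0.001748
C[C>A]T	0.017189	0.01815
G[C>A]A	0.017801	0.003264
G[C>A]C	0.063778	0.001186
G[C>A]G	0.064884	0.001497
G[C>A]T	0.032473	0.001762
T[C>A]A	0.038638	0.001515
T[C>A]C	0.001228	0.014481
T[C>A]G	0.015626	0.001132
T[C>A]T	0.014382	0.002781
A[C>G]A	0.003944	0.000355
A[C>G]C	0.000744	0.000608
A[C>G]G	0.000336	0.005041
A[C>G]T	0.011216	0.003727
C[C>G]A	0.000978	0.000543
C[C>G]C	0.00472	0.000199
C[C>G]G	5.8e-05	0.001056
C[C>G]T	0.001433	0.00788
G[C>G]A	0.003163	0.000329
G[C>G]C	0.002662	0.00544
G[C>G]G	0.005385	0.000676
G[C>G]T	0.000331	0.000101
T[C>G]A	0.000535	0.001032
T[C>G]C	0.000109	0.001621
T[C>G]G	6.5e-05	0.005512
T[C>G]T	4e-06	0.001897
A[C>T]A	0.00963	0.008359
A[C>T]C	0.0047	0.154678
A[C>T]G	0.003643	0.067911
A[C>T]T	0.000545	0.022924
C[C>T]A	0.000183	0.052941
C[C>T]C	0.001282	0.000589
C[C>T]G	0.000909	0.031489
C[C>T]T	0.000432	0.015912
G[C>T]A	0.000862	0.043792
G[C>T]C	9e-06	0.010886
G[C>T]G	0.000361	0.003883
G[C>T]T	0.00455	0.000302
T[C>T]A	0.014506	0.026054
T[C>T]C	0.004068	0.008691
T[C>T]G	0.014172	0.00387
T[C>T]T	0.005654	0.137458
A[T>A]A	0.00263	0.013192
A[T>A]C	0.000791	0.008927
A[T>A]G	0.010807	0.014323
A[T>A]T	0.010613	0.00048
C[T>A]A	0.001161	0.005952
C[T>A]C	0.000306	0.003608
C[T>A]G	0.008076	0.005609
C[T>A]T	0.000826	0.000346
G[T>A]A	0.011194	0.012736
G[T>A]C	0.005494	0.001787
G[T>A]G	0.000128	0.00115
G[T>A]T	0.001955	2.8e-05
T[T>A]A	0.003604	5e-05
T[T>A]C	0.017987	0.00316
T[T>A]G	0.013562	0.004034
T[T>A]T	0.000617	0.000694
A[T>C]A	0.00538	0.002445
A[T>C]C	0.006551	0.005412
A[T>C]G	0.00313	0.007932
A[T>C]T	0.000186	0.006728
C[T>C]A	0.032354	0.002545
C[T>C]C	0.015495	0.003542
C[T>C]G	0.002179	0.000233
C[T>C]T	0.006289	0.005408
G[T>C]A	0.005224	0.025341
G[T>C]C	0.001767	0.001957
G[T>C]G	0.000204	0.003715
G[T>C]T	0.000341	0.002531
T[T>C]A	0.000541	0.003619
T[T>C]C	3.9e-05	0.009635
T[T>C]G	0.000922	0.009432
T[T>C]T	0.015164	0.01349
A[T>G]A	0.000191	0.001482
A[T>G]C	0.014769	7.8e-05
A[T>G]G	0.006822	0.000195
A[T>G]T	0.003552	0.013838
C[T>G]A	0.013303	0.005969
C[T>G]C	0.003158	0.021469
C[T>G]G	0.018273	0.00388
C[T>G]T	0.008416	0.004478
G[T>G]A	0.007604	0.018538
G[T>G]C	0.006222	0.010539
G[T>G]G	0.001381	0.011176
G[T>G]T	0.000405	0.000404
T[T>G]A	0.002954	0.003801
T[T>G]C	0.000924	0.001706
T[T>G]G	0.001396	0.005885
T[T>G]T	0.007622	0.026741
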