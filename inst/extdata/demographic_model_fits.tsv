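model	ll	k	params	N_anc_printed
IM	-1193.96	7	theta=8683.75;s=1001.68;nu1=4.313377;nu2=10.06771;m12=10.16658;m21=2.99017;T=0.1041463;misid=0.043	2990.17
StrictIsolation	-1225.36	4	theta=8750.87;nu1=3.16734;nu2=14.33302;T=0.0691937;misid=0.043	3013.28
AncientSymmetricMigration	-1225.2	6	theta=8756.92;nu1=3.371614;nu2=9.837675;m=0.2412293;T1=0.01101856;T2=0.05869934;misid=0.043	3015.366
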