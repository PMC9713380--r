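variant_id	z_discovery	z_replication
syn_rs0001	-0.84011650356683831	-0.29754033981838585
syn_rs0002	6.5953669884301327	2.5798385566226258
syn_rs0003	-5.5645473241464032	-1.696404733352912
syn_rs0004	-5.5655613756816749	-2.5478267292942429
syn_rs0005	-6.4496193854666481	-3.6533511789445789
syn_rs0006	-6.0411939217497093	-2.687978283840204
syn_rs0007	-1.0989429813599965	-1.287420022402644
syn_rs0008	-5.7726637962709555	-3.7902779640600857
syn_rs0009	-6.4322832238151646	-2.8782943082164989
syn_rs0010	-3.235955326265251	-2.1617821636717447
syn_rs0011	-7.2949571578646264	-1.5431836825258975
syn_rs0012	5.4614265648391971	-0.17559632813740356
syn_rs0013	-5.7760629471524174	-2.5461432176904197
syn_rs0014	2.8863029218290399	1.8584682826946342
syn_rs0015	-1.1171851371273047	0.13189237267388487
syn_rs0016	6.072852771967181	2.9630617551968439
syn_rs0017	-2.2907048149891476	0.5462054295047476
syn_rs0018	5.8073309432456393	0.53141435838981543
syn_rs0019	5.4613730155274434	2.1425722330386359
syn_rs0020	5.6300723573466271	3.4440420550989863
syn_rs0021	0.78928311177511812	-0.081923194877784433
syn_rs0022	-5.4618388016001145	-0.051368193102897364
syn_rs0023	-1.9715169732179891	-1.8354651360658498
syn_rs0024	3.0256686781641751	1.6601134566274016
syn_rs0025	5.9883953941308743	2.8498797817999444
syn_rs0026	-5.7016089467070277	-1.7230912780477194
syn_rs0027	6.7231633594968327	3.9695387739071388
syn_rs0028	5.6518237831234206	3.839980912172936
syn_rs0029	-2.4767438358938572	-2.1031121545435139
syn_rs0030	-5.6440801419189768	-0.34332548339136992
syn_rs0031	6.4734358327306776	2.4013265162195632
syn_rs0032	5.6485909781506143	2.7399306809272663
syn_rs0033	0.91973044011618521	-0.43064764382205328
syn_rs0034	1.3875131231369371	1.1085171917708645
syn_rs0035	-5.923591856763136	-3.0773500367827569
syn_rs0036	-5.6920366693121309	-1.1996970032359318
syn_rs0037	-1.5449398483905188	-1.1821887071145702
syn_rs0038	6.7662842219308486	2.4941813674612736
syn_rs0039	-2.1567074200054921	-0.70133977163498584
syn_rs0040	0.33154560626925156	-1.3210860988946487
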