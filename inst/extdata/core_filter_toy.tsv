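epoc_id	euk_clade_id	candidate_label	elw	n_euk_labels	has_amorphea	has_diaphoretickes	category	pathway	sister_size
e01	1	Asgard	0.55	8	TRUE	TRUE	ribosome	ribosome	12
e01	1	Cyanobacteriota	0.42	8	TRUE	TRUE	ribosome	ribosome	9
e02	1	Asgard	0.55	8	TRUE	TRUE	ribosome	ribosome	12
e02	1	Cyanobacteriota	0.42	8	TRUE	TRUE	ribosome	ribosome	9
e03	1	Asgard	0.55	8	TRUE	TRUE	ribosome	ribosome	12
e03	1	Cyanobacteriota	0.42	8	TRUE	TRUE	ribosome	ribosome	9
e04	1	Asgard	0.55	8	TRUE	TRUE	ribosome	ribosome	12
e04	1	Cyanobacteriota	0.42	8	TRUE	TRUE	ribosome	ribosome	9
e05	1	Asgard	0.55	8	TRUE	TRUE	ribosome	ribosome	12
e05	1	Cyanobacteriota	0.42	8	TRUE	TRUE	ribosome	ribosome	9
e06	1	Asgard	0.6	9	TRUE	TRUE			10
e06	1	Bacillota	0.41	9	TRUE	TRUE			8
e07	1	Asgard	0.6	9	TRUE	TRUE			10
e07	1	Bacillota	0.41	9	TRUE	TRUE			8
e08	1	Asgard	0.6	5	TRUE	TRUE	glycolysis	glycolysis	10
e08	1	Myxococcota	0.41	5	TRUE	TRUE	glycolysis	glycolysis	7
e09	1	Asgard	0.6	5	TRUE	TRUE	glycolysis	glycolysis	10
e09	1	Myxococcota	0.41	5	TRUE	TRUE	glycolysis	glycolysis	7
e10	1	Asgard	0.6	7	TRUE	FALSE	proteasome	proteasome	10
e10	1	Actinomycetota	0.41	7	TRUE	FALSE	proteasome	proteasome	6
e11	1	Asgard	0.6	7	TRUE	FALSE	proteasome	proteasome	10
e11	1	Actinomycetota	0.41	7	TRUE	FALSE	proteasome	proteasome	6
e12	1	Asgard	0.85	9	TRUE	TRUE	dna_replication	dna_replication	15
e12	1	Thermococci	0.1	9	TRUE	TRUE	dna_replication	dna_replication	5
e13	1	Asgard	0.85	9	TRUE	TRUE	dna_replication	dna_replication	15
e13	1	Thermococci	0.1	9	TRUE	TRUE	dna_replication	dna_replication	5
e14	1	Asgard	0.3	9	TRUE	TRUE	glycolysis	glycolysis	10
e14	1	Bacteroidota	0.25	9	TRUE	TRUE	glycolysis	glycolysis	8
e15	1	Cyanobacteriota	0.995	9	TRUE	TRUE	glycolysis	glycolysis	11
e15	1	Asgard	0.005	9	TRUE	TRUE	glycolysis	glycolysis	10
e16	1	Alphaproteobacteria	1	7	TRUE	TRUE	oxidative_phosphorylation	oxidative_phosphorylation	22
e16	1	Asgard	0	7	TRUE	TRUE	oxidative_phosphorylation	oxidative_phosphorylation	10
e17	1	Asgard	0.72	15	TRUE	TRUE	ribosome	ribosome	20
e17	1	Halobacteria	0.27	15	TRUE	TRUE	ribosome	ribosome	5
e18	1	Asgard	0.705	15	TRUE	TRUE	ribosome	ribosome	19
e18	1	Halobacteria	0.29	15	TRUE	TRUE	ribosome	ribosome	5
e19	1	Asgard	0.71	14	TRUE	TRUE	ribosome	ribosome	30
e19	1	Halobacteria	0.28	14	TRUE	TRUE	ribosome	ribosome	5
e20	1	Asgard	0.7	20	TRUE	TRUE	ribosome	ribosome	40
e20	1	Halobacteria	0.29	20	TRUE	TRUE	ribosome	ribosome	5
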