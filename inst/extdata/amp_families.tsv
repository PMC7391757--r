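accession	family
AP00308	buforin
AP00489	buforin
AP02811	acipensin
AP02813	acipensin
AP02096	ubiquicidin
AP02766	lysozyme
AP02533	beta_thymosin
AP01555	crustin
AP02625	crustin
AP02752	crustin
AP02753	crustin
AP02959	paralithocin
AP02960	paralithocin
AP02961	paralithocin
AP03038	kazal
AP02147	alf
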