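study	method	n_samples
Klatte2009	GPG	246
Beroud1996	qPCR	118
Gunawan2001	G-Banding	118
Toma2008	SNP10K	22
Yoshimoto2007	BACPAC	26
Current	SNP100K	42
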