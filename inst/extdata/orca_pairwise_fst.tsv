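pop	SR	AR	BS	AT	CT	MI
SR	0	0.2475	0.21784	0.72847	0.73832	0.79715
AR	0.1632	0	0.05128	0.67336	0.6764	0.73618
BS	0.1363	0.04735	0	0.64762	0.64937	0.71197
AT	0.29719	0.26584	0.23356	0	0.05099	0.31034
CT	0.29339	0.25936	0.22429	0.0346	0	0.25045
MI	0.33442	0.30703	0.27442	0.17709	0.15502	0
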