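pair	tm_expected
rel01	0.858234
rel02	0.862263
rel03	0.851778
rel04	0.857118
rel05	0.850784
unr01	0.113527
unr02	0.173761
unr03	0.161119
unr04	0.159442
unr05	0.16437
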