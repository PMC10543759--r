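disease	microbe
disease_01	microbe_004
disease_01	microbe_006
disease_02	microbe_004
disease_02	microbe_006
disease_03	microbe_003
disease_03	microbe_005
disease_03	microbe_008
disease_03	microbe_010
disease_05	microbe_003
disease_05	microbe_005
disease_05	microbe_008
disease_05	microbe_010
disease_06	microbe_004
disease_06	microbe_006
disease_06	microbe_007
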