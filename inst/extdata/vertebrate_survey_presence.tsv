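species	state
Atlantic_hagfish	absent
Inshore_hagfish	absent
Sea_lamprey	present
Japanese_lamprey	present
Short_headed_lamprey	absent
Pouched_lamprey	absent
Elephant_shark	absent
Thornback_ray	absent
Lesser_spotted_dogfish	absent
Beluga_sturgeon	absent
Florida_spotted_gar	absent
Zebrafish	absent
European_chub	present
Barbel	present
Northern_pike	present
Atlantic_salmon	present
Lake_trout	present
Grayling	present
Medaka	absent
Green_spotted_pufferfish	absent
Stickleback	absent
European_perch	present
Walleye	absent
African_cichlid	absent
Bullhead	absent
African_clawed_frog	absent
Soft_shelled_turtle	absent
Siamese_crocodile	absent
Japanese_quail	absent
Mouse	absent
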