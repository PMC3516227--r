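(((Atlantic_hagfish,Inshore_hagfish),((Sea_lamprey,Japanese_lamprey),(Short_headed_lamprey,Pouched_lamprey))),((Elephant_shark,(Thornback_ray,Lesser_spotted_dogfish)),((Beluga_sturgeon,(Florida_spotted_gar,((Zebrafish,(European_chub,Barbel)),((Northern_pike,(Atlantic_salmon,(Lake_trout,Grayling))),((Medaka,Green_spotted_pufferfish),(Stickleback,(European_perch,(Walleye,(African_cichlid,Bullhead))))))))),(African_clawed_frog,((Soft_shelled_turtle,(Siamese_crocodile,Japanese_quail)),Mouse)))));
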