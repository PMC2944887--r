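# Grasshopper resurvey abundance table: Front Range (Colorado) elevational gradient.
# baseline_mean is the average number of individuals collected per season in the
# 1959-1960 surveys (A1: 1959 only); diff_YYYY is the change in the within-overlap-
# window seasonal total in resurvey year YYYY relative to baseline_mean; blank =
# site not surveyed that year. verified=no marks cells that are typographically
# garbled in the printed source and should be excluded from inference.
site,species,baseline_mean,diff_2006,diff_2007,diff_2008,verified
Chautauqua,Aeropedellus clavatus,233,,-123,-148,yes
Chautauqua,Melanoplus confusus,36,,-23,-20,yes
Chautauqua,Melanoplus sanguinipes,139,,-100,-108,yes
Chautauqua,Melanoplus bivittatus,189,,94,453,yes
Chautauqua,Melanoplus dawsoni,57,,-26,-6,no
Chautauqua,Hesperotettix viridis,83,,-42,-26,yes
A1,Aeropedellus clavatus,10,,12,19,yes
A1,Melanoplus confusus,67,,-52,23,yes
A1,Melanoplus dodgei,146,,-79,-56,yes
A1,Melanoplus sanguinipes,256,,-217,-175,yes
A1,Cratypedes neglectus,165,,-122,-54,yes
A1,Camnula pellucida,64,,-46,-40,yes
A1,Hesperotettix viridis,127,,-88,-53,yes
A1,Melanoplus bivittatus,37,,-23,-4,yes
A1,Trimerotropis cincta,66,,-58,-50,yes
B1,Aeropedellus clavatus,206,-91,-120,-59,yes
B1,Melanoplus dodgei,244,-163,-149,-102,yes
B1,Camnula pellucida,91,-62,-74,-37,yes
B1,Circotettix rabula,10,11,0,37,yes
B1,Melanoplus dawsoni,111,-32,-78,-40,yes
B1,Melanoplus packardii,12,332,104,259,yes
B1,Chloealtis abdominalis,10,2,-1,13,yes
C1,Melanoplus dodgei,90,95,-7,22,yes
C1,Melanoplus fasciatus,83,-14,24,-41,yes
C1,Camnula pellucida,83,893,-16,48,yes
C1,Chloealtis abdominalis,15,64,0,24,yes
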