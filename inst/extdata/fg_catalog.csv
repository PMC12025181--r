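code,habitat,representative_taxa,tolerance,susceptibility,dominant_in_study
A,"Oligotrophic, clean, deep water","Rhizosolenia sp.","Low nutrients","Elevated pH",FALSE
B,"Mesotrophic trophic, small-to-medium, or large shallow-water bodies","Cyclotella sp.","Low light","Elevated pH, water stratification",TRUE
C,"Eutrophic, small- and medium-sized reservoirs","Asterionella sp.","Low light","Water stratification",FALSE
D,"Rich in nutrients, cloudy","Synedra sp.; Nitzschia sp.","Scouring","Nutrient deficiency",TRUE
E,"Oligotrophic or heterotrophic type, small water bodies, shallow water","Dinobryon divergens","Low nutrients","CO2 deficiency",FALSE
F,"Mesotrophic-to-eutrophic, clean, and strong water mixing","Oocystis sp.; Kirchneriella sp.","Low nutrients","CO2 deficiency",FALSE
G,"Eutrophic, stagnant water bodies","Eudorina sp.; Pandorina sp.","High light","Nutrient salt deficiency",FALSE
H1,"Eutrophic, stratified, low nitrogen content","Anabaena sp.; Aphanizomenon sp.","Low carbon/nitrogen content","Water mixing, low light, low phosphorus",FALSE
J,"High nutrient, mixed, shallow water","Scenedesmus sp.; Crucigenia sp.; Tetraedron sp.","","High light",FALSE
K,"Eutrophic, shallow water","Aphanocapsa sp.","","Strong water mixing",FALSE
L_M,"Eutrophic to hypereutrophic, small- and medium-sized water bodies","Dactylococcopsis sp.; Ceratium sp.","Extremely low carbon content","Water mixing, low light",FALSE
L_O,"Mesotrophic-to-eutrophic, medium-to-large water bodies, can be deep or shallow","Merismopedia sp.; Chroococcus sp.; Peridinium sp.","Nutrient stratification","Prolonged/deep mixing",TRUE
MP,"Frequent agitation, turbidity, shallow water","Oscillatoria sp.; Navicula sp.; Achnanthes sp.","Mixing disturbance","",FALSE
N,"Continuous or semi-continuous mixed bodies of water","Cosmarium sp.","Low nutrients","Water stratification, elevated pH",FALSE
P,"It is similar to functional group N, but the trophic status of the water body is higher","Melosira sp.; Fragilaria sp.; Closterium sp.","Low light, low carbon content","Water stratification, silicon deficiency",TRUE
S1,"The mixture is cloudy and has low transparency","Pseudanabaena limnetica; Rhabdogloea sp.; Limnothrix sp.","Extremely low light","Scouring",TRUE
S2,"Warm, highly alkaline, shallow water","Spirulina sp.","Low light","Scouring",FALSE
S_N,"Warm, blended","Cylindrospermum raciborskii; Raphidiopsis sp.","Low light, low nutrients","Scouring",FALSE
T,"Mix water bodies continuously","Mougeotia sp.; Quadrigula chodatii","Low light","Nutrient deficiency",FALSE
TC,"Eutrophication, still or flowing water, with upright plants","Lyngbya sp.","","Scouring",FALSE
W1,"Organic pollution, shallow water","Euglena sp.; Euglena oxyuris","High biochemical oxygen demand (BOD)","Grazing pressure",TRUE
W2,"Mesotrophic nutrition, shallow water","Trachelomonas sp.","","",TRUE
X1,"Super nutritious, shallow water","Chlorella sp.; Ankistrodesmus sp.","Water stratification","Nutrient deficiency, filter feeding",FALSE
X2,"Mesotrophic-to-eutrophic, shallow water","Chlamydomonas sp.","Water stratification","Water mixing, filter feeding",FALSE
X3,"Oligotrophic, mixed, shallow water","Schroederia sp.","Harsh environmental conditions","Water mixing, grazing pressure",FALSE
Y,"Still-water environment","Cryptomonas sp.; Gymnodinium sp.","Low light","Predation",TRUE
Z,"Oligotrophic","Synechococcus sp.","Low nutrients","Low light, grazing pressure",FALSE
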