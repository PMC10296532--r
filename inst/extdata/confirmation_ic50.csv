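compound_id,generic_name,compound_group,ic50_1455,ic50_1458
SN01006330,7 8-Dimethoxyflavone,anti-inflammatory,0.08,0.19
SN01005561,Aminothiazole,anti-microbial,0.12,2.08
SN01005320,Benazepril HCl,anti-hypertensive,9.37,0.06
SN01005071,Ceftibuten,anti-microbial,2.29,0.07
SN00852779,Chlordiazepoxide,anti-depressant,0.02,0.08
SN01005451,Chloroquinalol,anti-microbial,>20,0.08
SN01006117,Cytidine triphosphate disodium,anti-inflammatory,0.02,0.08
SN01005419,Editol,anti-inflammatory,ND,0.87
SN01004366,Hydroxyzine Pamoate,anti-histamine,0.02,ND
SN01004587,Indoprofen,anti-inflammatory,0.02,0.001
SN01004583,Ketotifen Fumarate,anti-histamine,0.22,ND
SN01005061,Pantoprazole,proton pump inhibitor,0.19,0.37
SN01005391,Pregabalin,anti-inflammatory,0.08,0.08
SN01004486,Promazine HCl,anti-psychotic,0.02,0.15
SN01005316,Repaglinide,anti-diabetic,>20,0.07
SN01005445,Sildenafil Citrate,anti-inflammatory,1.88,0.96
SN01004511,Spectinomycin HCl,anti-microbial,0.02,ND
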