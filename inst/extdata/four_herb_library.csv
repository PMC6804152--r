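id,name,formula,class,subclass,source_herb,aglycone,sugar_composition,loss_sequence,malonyl,acetyl,expected_rt,reference_standard
noto_r1,Notoginsenoside R1,C47H80O18,ginsenoside,PPT,NRR,PPT,Glc:2;Pen:1,Glc;Pen;Glc,0,0,5.74,TRUE
rg1,Ginsenoside Rg1,C42H72O14,ginsenoside,PPT,NRR,PPT,Glc:2,Glc;Glc,0,0,6.35,TRUE
re,Ginsenoside Re,C48H82O18,ginsenoside,PPT,NRR,PPT,Glc:2;Rha:1,Rha;Glc;Glc,0,0,6.40,TRUE
rb1,Ginsenoside Rb1,C54H92O23,ginsenoside,PPD,NRR,PPD,Glc:4,Glc;Glc;Glc;Glc,0,0,11.20,TRUE
rd,Ginsenoside Rd,C48H82O18,ginsenoside,PPD,NRR,PPD,Glc:3,Glc;Glc;Glc,0,0,13.95,TRUE
noto_r2,Notoginsenoside R2,C41H70O13,ginsenoside,PPT,NRR,PPT,Glc:1;Pen:1,Pen;Glc,0,0,11.50,TRUE
rh1,Ginsenoside Rh1,C36H62O9,ginsenoside,PPT,NRR,PPT,Glc:1,Glc,0,0,15.00,TRUE
gyp17,Gypenoside XVII,C48H82O18,ginsenoside,PPD,NRR,PPD,Glc:3,Glc;Glc;Glc,0,0,15.10,TRUE
mal_rb1,Malonylginsenoside Rb1,C57H94O26,ginsenoside,malonyl,NRR,PPD,Glc:4,,1,0,11.97,TRUE
mal_rd,Malonylginsenoside Rd,C51H84O21,ginsenoside,malonyl,NRR,PPD,Glc:3,,1,0,15.51,FALSE
ro,Ginsenoside Ro,C48H76O19,ginsenoside,OA,NRR,OA,Glc:2;GlurA:1,Glc;Glc;H2O;CO2;HCOOH,0,0,12.37,TRUE
stip_r2,Stipuleanoside R2,C53H84O23,ginsenoside,OA,NRR,OA,Glc:2;GlurA:1;Pen:1,Glc;Pen;Glc;H2O;CO2;HCOOH,0,0,12.46,FALSE
re1,Ginsenoside Re1,C48H82O19,ginsenoside,PPT,NRR,PPT,Glc:3,Glc;Glc;Glc,0,0,,FALSE
re2,Ginsenoside Re2,C48H82O19,ginsenoside,PPT,NRR,PPT,Glc:3,Glc;Glc;Glc,0,0,,FALSE
re3,Ginsenoside Re3,C48H82O19,ginsenoside,PPT,NRR,PPT,Glc:3,Glc;Glc;Glc,0,0,,FALSE
noto_r3,Notoginsenoside R3,C48H82O19,ginsenoside,PPT,NRR,PPT,Glc:3,Glc;Glc;Glc,0,0,,FALSE
noto_r6,Notoginsenoside R6,C48H82O19,ginsenoside,PPT,NRR,PPT,Glc:3,Glc;Glc;Glc,0,0,,FALSE
noto_m,Notoginsenoside M,C48H82O19,ginsenoside,PPT,NRR,PPT,Glc:3,Glc;Glc;Glc,0,0,,FALSE
chik_lm4,Chikusetsusaponin LM4,C48H82O19,ginsenoside,PPT,NRR,PPT,Glc:3,Glc;Glc;Glc,0,0,,FALSE
ast_iv,Astragaloside IV,C41H68O14,astragaloside,cycloastragenol glycoside,AR,cycloastragenol,Glc:1;Pen:1,Pen;Glc,0,0,12.90,TRUE
ast_iii,Astragaloside III,C41H68O14,astragaloside,cycloastragenol glycoside,AR,cycloastragenol,Glc:1;Pen:1,Glc;Pen,0,0,13.18,TRUE
ast_ii,Astragaloside II,C43H70O15,astragaloside,cycloastragenol glycoside,AR,cycloastragenol,Glc:1;Pen:1,,0,1,15.26,TRUE
ast_i,Astragaloside I,C45H72O16,astragaloside,cycloastragenol glycoside,AR,cycloastragenol,Glc:1;Pen:1,,0,2,19.19,TRUE
iso_ast_i,Isoastragaloside I,C45H72O16,astragaloside,cycloastragenol glycoside,AR,cycloastragenol,Glc:1;Pen:1,,0,2,20.18,TRUE
soy_i,Soyasaponin I,C48H78O18,astragaloside,soyasaponin,AR,soyasapogenol,Glc:1;Rha:1;GlurA:1,H2O;Glc;Rha,0,0,16.22,TRUE
danshensu,Danshensu,C9H10O5,phenolic_acid,danshensu,SMRR,,,H2O;CO2,0,0,2.03,TRUE
sal_b,Salvianolic acid B,C36H30O16,phenolic_acid,salvianolic acid,SMRR,,,danshensu;danshensu,0,0,6.72,TRUE
sal_a,Salvianolic acid A,C26H22O10,phenolic_acid,salvianolic acid,SMRR,,,danshensu,0,0,7.70,TRUE
litho_a,Lithospermic acid,C27H22O12,phenolic_acid,salvianolic acid,SMRR,,,danshensu,0,0,4.96,FALSE
tan_i,Tanshinone I,C18H12O3,tanshinone,abietane diterpenoid,SMRR,,,,0,0,24.14,TRUE
tan_i_iso,Tanshinone I isomer,C18H12O3,tanshinone,abietane diterpenoid,SMRR,,,,0,0,23.57,FALSE
cryptotan,Cryptotanshinone,C19H12O3,tanshinone,abietane diterpenoid,SMRR,,,,0,0,24.21,TRUE
tan_iia,Tanshinone IIA,C19H18O3,tanshinone,abietane diterpenoid,SMRR,,,,0,0,25.96,TRUE
formononetin,Formononetin,C16H12O4,flavonoid,isoflavone,AR,,,,0,0,21.50,TRUE
calycosin_glc,Calycosin-7-O-glucoside,C22H22O10,flavonoid,isoflavone glycoside,AR,,Glc:1,,0,0,4.10,TRUE
campanulin,Campanulin,C22H22O10,flavonoid,isoflavone glycoside,AR,,Glc:1,,0,0,3.80,FALSE
aucubin,Aucubin,C15H22O9,iridoid,iridoid glycoside,SR,,Glc:1,,0,0,1.62,TRUE
harpagide,Harpagide,C15H24O10,iridoid,iridoid glycoside,SR,,Glc:1,,0,0,1.87,TRUE
harpagoside,Harpagoside,C24H30O11,iridoid,iridoid glycoside,SR,,Glc:1,,0,0,7.98,TRUE
angoroside_c,Angoroside C,C36H48O19,phenylpropanoid,phenylethanoid glycoside,SR,,Glc:1;Rha:1,feruloyl;Rha;H2O,0,0,5.26,FALSE
coum_sucrose,6-O-p-Coumaroylsucrose,C21H28O13,phenylpropanoid,coumaroyl sucrose ester,SR,,Glc:1,Glc,0,0,2.82,FALSE
oleanolic_acid,Oleanolic acid,C30H48O3,other,sapogenin,unknown,OA,,,0,0,,FALSE
cycloastragenol,Cycloastragenol,C30H50O5,other,sapogenin,AR,cycloastragenol,,,0,0,,FALSE
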