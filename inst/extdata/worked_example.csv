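"sequence","annotation_text","activity_value","activity_unit","source"
"KWKLFKKIGAVL","acute myeloid leukemia, HL-60",12,"uM","synthetic"
"FAKKLAKKLLKF","T-cell leukemia, Jurkat",800,"nM","synthetic"
"GLFDIIKKIAES","lymphoma, U937",,,"synthetic"
"ALWKTMLKKLGT","glioblastoma multiforme, U87",25,"uM","synthetic"
"KLAKLAKKLAKL","neuroblastoma, SH-SY5Y",,,"synthetic"
"GIGKFLHSAKKF","astrocytoma",,,"synthetic"
"KWKSFLKTFKSA","breast adenocarcinoma, MCF-7",64,"uM","synthetic"
"kwksflktfksa","breast adenocarcinoma, MCF-7",32,"uM","synthetic"
"FLPIIAKLLSGL","breast carcinoma, MDA-MB-231",5,"uM","synthetic"
"ILPWKWPWWPWR","mammary carcinoma, T47D",,,"synthetic"
"SWLSKTAKKLEN","cervical carcinoma, HeLa",0.02,"mM","synthetic"
"FFGWLIKGAIHA","cervical cancer, SiHa",,,"synthetic"
"GWGSFFKKAAHV","colorectal carcinoma, HT-29",18,"uM","synthetic"
"VNWKKILGKIIK","colon adenocarcinoma, HCT116",,,"synthetic"
"KWKSFLKTFKSA","colon carcinoma, SW480",,,"synthetic"
"FLGALFKALSKL","hepatocellular carcinoma, HepG2",9,"uM","synthetic"
"GLWSKIKEVGKE","hepatoma, SMMC-7721",,,"synthetic"
"AFDIIKKIAESF","lung adenocarcinoma, A549",30,"uM","synthetic"
"RWKIFKKIEKVG","non-small cell lung cancer, NCI-H460",,,"synthetic"
"ILGKIWEGIKSL","Lewis lung carcinoma",,,"synthetic"
"FAKLLAKLAKKL","prostate carcinoma, PC-3",14,"uM","synthetic"
"GLLDIVKKVVGA","prostate cancer, DU145",,,"synthetic"
"KIKWFKTMKSLR","melanoma, A375",7,"uM","synthetic"
"DSHAKRHHGYKR","murine melanoma, B16",,,"synthetic"
"GFKRIVQRIKDF","skin squamous cell carcinoma",,,"synthetic"
"ACXKLLKKWWRR","breast adenocarcinoma, MCF-7",,,"synthetic"
"KWKLFKK","cervical carcinoma, HeLa",,,"synthetic"
"GLPALISWSKRK","breast and lung carcinoma",,,"synthetic"
"RRWWRRWWRRWW","osteosarcoma, MG-63",,,"synthetic"
"VDKPPYLPRPRP","gastric carcinoma, AGS",1,"ug/mL","synthetic"
"KKVVFKVKFKGG","leukemia, K562",,,"synthetic"
"PAWRKAFRWAWR","glioma, U251",,,"synthetic"
"GLFGVLAKVAAH","cervical cancer, CaSki",,,"synthetic"
"LLGDFFRKSKEK","hepatocellular carcinoma, Huh-7",,,"synthetic"
"SKITDILAKLGK","prostate cancer, LNCaP",,,"synthetic"
"WKLFKKILKVLG","colon carcinoma, LoVo",,,"synthetic"
"HGVSGHGQHGVH","melanoma, SK-MEL-28",,,"synthetic"
"TFFRLFNRSFTQ","breast carcinoma, 4T1",,,"synthetic"
"IDWKKLLDAAKQ","lung carcinoma, Calu-3",,,"synthetic"
"NGVQPKYKWWKW","multiple myeloma",,,"synthetic"
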