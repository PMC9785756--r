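"id","concentration_mg_L","replicate","response","response_type","is_control"
"SMX",0,1,498470.6,"cells_per_ml",TRUE
"SMX",0,2,514153.1,"cells_per_ml",TRUE
"SMX",0,3,547985.2,"cells_per_ml",TRUE
"SMX",0.1,1,469706.7,"cells_per_ml",FALSE
"SMX",0.1,2,481015.3,"cells_per_ml",FALSE
"SMX",0.1,3,497918.3,"cells_per_ml",FALSE
"SMX",0.3,1,391035.3,"cells_per_ml",FALSE
"SMX",0.3,2,418562.2,"cells_per_ml",FALSE
"SMX",0.3,3,398132,"cells_per_ml",FALSE
"SMX",0.5,1,300895.9,"cells_per_ml",FALSE
"SMX",0.5,2,308230,"cells_per_ml",FALSE
"SMX",0.5,3,296209.4,"cells_per_ml",FALSE
"SMX",0.7,1,204933.3,"cells_per_ml",FALSE
"SMX",0.7,2,234177.2,"cells_per_ml",FALSE
"SMX",0.7,3,213023.2,"cells_per_ml",FALSE
"SMX",0.9,1,123618.3,"cells_per_ml",FALSE
"SMX",0.9,2,134969.5,"cells_per_ml",FALSE
"SMX",0.9,3,159002,"cells_per_ml",FALSE
"SMX",1.2,1,119463.1,"cells_per_ml",FALSE
"SMX",1.2,2,95596.3,"cells_per_ml",FALSE
"SMX",1.2,3,105320,"cells_per_ml",FALSE
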