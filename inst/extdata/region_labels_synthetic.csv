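"section","cell","status","evidence","confidence"
"A",1,"intact","intact_function","figure"
"A",2,"intact","intact_function","figure"
"A",3,"intact","intact_function","figure"
"A",4,"damaged","oxidative_stress","text"
"A",5,"intact","intact_function","figure"
"A",6,"damaged","oxidative_stress","text"
"A",7,"intact","intact_function","figure"
"A",8,"intact","intact_function","figure"
"A",9,"intact","intact_function","figure"
"B",1,"intact","behavioural_deficit","text"
"B",2,"intact","intact_function","text"
"B",3,"intact","behavioural_deficit","text"
"B",4,"intact","intact_function","figure"
"B",5,"intact","intact_function","figure"
"B",6,"intact","intact_function","figure"
"B",7,"intact","intact_function","figure"
"B",8,"intact","intact_function","figure"
"B",9,"intact","intact_function","figure"
"C",1,"damaged","oxidative_stress","text"
"C",2,"intact","intact_function","text"
"C",3,"damaged","oxidative_stress","text"
"C",4,"intact","intact_function","figure"
"C",5,"intact","intact_function","figure"
"C",6,"intact","intact_function","figure"
"C",7,"intact","intact_function","figure"
"C",8,"intact","intact_function","figure"
"C",9,"intact","intact_function","figure"
"D",1,"intact","behavioural_deficit","text"
"D",2,"intact","intact_function","text"
"D",3,"intact","behavioural_deficit","text"
"D",4,"intact","intact_function","figure"
"D",5,"intact","intact_function","figure"
"D",6,"intact","intact_function","figure"
"D",7,"intact","intact_function","text"
"D",8,"intact","intact_function","figure"
"D",9,"intact","intact_function","text"
"E",1,"intact","intact_function","figure"
"E",2,"intact","intact_function","figure"
"E",3,"intact","intact_function","figure"
"E",4,"intact","intact_function","figure"
"E",5,"damaged","oxidative_stress","figure"
"E",6,"intact","intact_function","figure"
"E",7,"intact","intact_function","figure"
"E",8,"damaged","oxidative_stress","text"
"E",9,"intact","intact_function","figure"
"F",1,"intact","intact_function","figure"
"F",2,"intact","intact_function","figure"
"F",3,"intact","intact_function","figure"
"F",4,"damaged","oxidative_stress","text"
"F",5,"intact","intact_function","figure"
"F",6,"damaged","oxidative_stress","text"
"F",7,"intact","intact_function","figure"
"F",8,"unlabeled","","figure"
"F",9,"intact","intact_function","figure"
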