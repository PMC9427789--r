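"chain","resno","icode","aa"
"H",1,"","E"
"H",2,"","V"
"H",3,"","Q"
"H",4,"","L"
"H",5,"","V"
"H",6,"","E"
"H",7,"","S"
"H",8,"","G"
"H",9,"","G"
"H",10,"","G"
"H",11,"","L"
"H",12,"","V"
"H",13,"","Q"
"H",14,"","P"
"H",15,"","G"
"H",16,"","G"
"H",17,"","S"
"H",18,"","L"
"H",19,"","R"
"H",20,"","L"
"H",21,"","S"
"H",22,"","C"
"H",23,"","A"
"H",24,"","A"
"H",25,"","S"
"H",26,"","G"
"H",27,"","F"
"H",28,"","T"
"H",29,"","F"
"H",30,"","S"
"H",31,"","S"
"H",32,"","Y"
"H",33,"","Y"
"H",34,"","M"
"H",35,"","H"
"H",36,"","W"
"H",37,"","V"
"H",38,"","R"
"H",39,"","Q"
"H",40,"","A"
"H",41,"","P"
"H",42,"","G"
"H",43,"","K"
"H",44,"","G"
"H",45,"","L"
"H",46,"","E"
"H",47,"","W"
"H",48,"","V"
"H",49,"","A"
"H",50,"","I"
"H",51,"","I"
"H",52,"","S"
"H",53,"","Y"
"H",54,"","D"
"H",55,"","G"
"H",56,"","S"
"H",57,"","N"
"H",58,"","T"
"H",59,"","S"
"H",60,"","Y"
"H",61,"","A"
"H",62,"","D"
"H",63,"","S"
"H",64,"","V"
"H",65,"","K"
"H",66,"","G"
"H",67,"","R"
"H",68,"","F"
"H",69,"","T"
"H",70,"","I"
"H",71,"","S"
"H",72,"","R"
"H",73,"","D"
"H",74,"","N"
"H",75,"","S"
"H",76,"","K"
"H",77,"","N"
"H",78,"","T"
"H",79,"","L"
"H",80,"","Y"
"H",81,"","L"
"H",82,"","Q"
"H",83,"","M"
"H",84,"","N"
"H",85,"","S"
"H",86,"","L"
"H",87,"","R"
"H",88,"","A"
"H",89,"","E"
"H",90,"","D"
"H",91,"","T"
"H",92,"","A"
"H",93,"","V"
"H",94,"","R"
"H",95,"","D"
"H",96,"","S"
"H",97,"","V"
"H",98,"","D"
"H",99,"","G"
"H",100,"","Y"
"H",101,"","D"
"H",102,"","I"
"H",103,"","W"
"H",104,"","G"
"H",105,"","Q"
"H",106,"","G"
"H",107,"","T"
"H",108,"","L"
"H",109,"","V"
"H",110,"","T"
"L",1,"","D"
"L",2,"","I"
"L",3,"","Q"
"L",4,"","M"
"L",5,"","T"
"L",6,"","Q"
"L",7,"","S"
"L",8,"","P"
"L",9,"","S"
"L",10,"","S"
"L",11,"","L"
"L",12,"","S"
"L",13,"","A"
"L",14,"","S"
"L",15,"","V"
"L",16,"","G"
"L",17,"","D"
"L",18,"","R"
"L",19,"","V"
"L",20,"","T"
"L",21,"","I"
"L",22,"","T"
"L",23,"","C"
"L",24,"","Q"
"L",25,"","A"
"L",26,"","S"
"L",27,"","Q"
"L",28,"","D"
"L",29,"","I"
"L",30,"","S"
"L",31,"","N"
"L",32,"","A"
"L",33,"","L"
"L",34,"","N"
"L",35,"","W"
"L",36,"","Y"
"L",37,"","Q"
"L",38,"","Q"
"L",39,"","K"
"L",40,"","P"
"L",41,"","G"
"L",42,"","K"
"L",43,"","A"
"L",44,"","P"
"L",45,"","K"
"L",46,"","L"
"L",47,"","L"
"L",48,"","I"
"L",49,"","Y"
"L",50,"","D"
"L",51,"","A"
"L",52,"","S"
"L",53,"","N"
"L",54,"","L"
"L",55,"","E"
"L",56,"","T"
"L",57,"","G"
"L",58,"","V"
"L",59,"","P"
"L",60,"","S"
"L",61,"","R"
"L",62,"","F"
"L",63,"","S"
"L",64,"","G"
"L",65,"","S"
"L",66,"","G"
"L",67,"","S"
"L",68,"","G"
"L",69,"","T"
"L",70,"","D"
"L",71,"","F"
"L",72,"","T"
"L",73,"","F"
"L",74,"","T"
"L",75,"","I"
"L",76,"","S"
"L",77,"","S"
"L",78,"","L"
"L",79,"","Q"
"L",80,"","P"
"L",81,"","E"
"L",82,"","D"
"L",83,"","I"
"L",84,"","A"
"L",85,"","T"
"L",86,"","Y"
"L",87,"","Y"
"L",88,"","C"
"L",89,"","Q"
"L",90,"","Q"
"L",91,"","Y"
"L",92,"","D"
"L",93,"","N"
"L",94,"","L"
"L",95,"","P"
"L",96,"","F"
"L",97,"","T"
"L",98,"","F"
"L",99,"","G"
"L",100,"","Q"
"L",101,"","G"
"L",102,"","T"
"L",103,"","K"
"L",104,"","V"
"L",105,"","E"
"L",106,"","I"
"L",107,"","K"
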