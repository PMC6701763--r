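population,locality,site,phase_years,n,haplotype,count
Chulym,Shaidurovo,14,"rising 2015; 2016",12,I,5
Chulym,Shaidurovo,14,"rising 2015; 2016",12,II,5
Chulym,Shaidurovo,14,"rising 2015; 2016",12,III,2
Chulym,Bazovo,15,"rising 2015; 2016",26,I,14
Chulym,Bazovo,15,"rising 2015; 2016",26,II,8
Chulym,Bazovo,15,"rising 2015; 2016",26,III,3
Chulym,Bazovo,15,"rising 2015; 2016",26,IIe,1
Chulym,noname-16,16,"rising 2015; 2016",12,I,5
Chulym,noname-16,16,"rising 2015; 2016",12,II,2
Chulym,noname-16,16,"rising 2015; 2016",12,III,3
Chulym,noname-16,16,"rising 2015; 2016",12,IIIb,1
Chulym,noname-16,16,"rising 2015; 2016",12,IIIc,1
Chany,Starye Karachi,1,"rising 2015",4,I,2
Chany,Starye Karachi,1,"rising 2015",4,II,1
Chany,Starye Karachi,1,"rising 2015",4,IIIa,1
Chany,noname-2,2,"rising 2015",1,I,1
Chany,Chany,3,"rising 2015; 2016",16,I,5
Chany,Chany,3,"rising 2015; 2016",16,II,4
Chany,Chany,3,"rising 2015; 2016",16,III,6
Chany,Chany,3,"rising 2015; 2016",16,IV,1
Omsk,Tatarsk,4,"peak 2015; decline 2016",23,I,9
Omsk,Tatarsk,4,"peak 2015; decline 2016",23,II,10
Omsk,Tatarsk,4,"peak 2015; decline 2016",23,III,2
Omsk,Tatarsk,4,"peak 2015; decline 2016",23,Ia,1
Omsk,Tatarsk,4,"peak 2015; decline 2016",23,IIa,1
Omsk,Krasny Yar,5,"decline 2015; 2016",20,I,9
Omsk,Krasny Yar,5,"decline 2015; 2016",20,II,7
Omsk,Krasny Yar,5,"decline 2015; 2016",20,III,2
Omsk,Krasny Yar,5,"decline 2015; 2016",20,Ib,1
Omsk,Krasny Yar,5,"decline 2015; 2016",20,IIb,1
Omsk,Lubinsky,6,"peak 2015; decline 2016",15,I,4
Omsk,Lubinsky,6,"peak 2015; decline 2016",15,II,7
Omsk,Lubinsky,6,"peak 2015; decline 2016",15,III,3
Omsk,Lubinsky,6,"peak 2015; decline 2016",15,IIa,1
Ishim,Novolokti,7,"decline 2015",2,I,1
Ishim,Novolokti,7,"decline 2015",2,II,1
Ishim,Loktyash,8,"decline 2015",1,II,1
Ishim,Berduzhie,9,"decline 2015; 2016",10,I,6
Ishim,Berduzhie,9,"decline 2015; 2016",10,II,3
Ishim,Berduzhie,9,"decline 2015; 2016",10,IIIa,1
Ishim,Bolshoy Krasnoyar,13,"decline 2015",2,I,1
Ishim,Bolshoy Krasnoyar,13,"decline 2015",2,II,1
Tyumen,Kyshtyrla,10,"decline 2015",1,I,1
Tyumen,noname-11,11,"decline 2015; peak 2016",30,I,14
Tyumen,noname-11,11,"decline 2015; peak 2016",30,II,12
Tyumen,noname-11,11,"decline 2015; peak 2016",30,III,2
Tyumen,noname-11,11,"decline 2015; peak 2016",30,IIc,1
Tyumen,noname-11,11,"decline 2015; peak 2016",30,IId,1
Tyumen,Kirovskiy,12,"decline 2015; peak 2016",33,I,18
Tyumen,Kirovskiy,12,"decline 2015; peak 2016",33,II,8
Tyumen,Kirovskiy,12,"decline 2015; peak 2016",33,III,6
Tyumen,Kirovskiy,12,"decline 2015; peak 2016",33,Ic,1
Trans-Ural,Kamensk-Uralsky,19,"troughs 2015",5,I,2
Trans-Ural,Kamensk-Uralsky,19,"troughs 2015",5,II,2
Trans-Ural,Kamensk-Uralsky,19,"troughs 2015",5,III,1
Trans-Ural,Chebarkul,22,"troughs 2016",7,I,1
Trans-Ural,Chebarkul,22,"troughs 2016",7,II,2
Trans-Ural,Chebarkul,22,"troughs 2016",7,III,3
Trans-Ural,Chebarkul,22,"troughs 2016",7,IIf,1
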