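isolate_id,colony_morphology,aerial_mycelia,substrate_mycelia,diffusible_pigment,color_series,texture,tissue,genus
DNRA1,"Irregular, umbonate",Gray,Gray,NP,Gray,Dry,Root,Streptomyces
DNRA2,"Irregular, raised",White,White,NP,White,Rough,Root,
DNRA3,Irregular flat,White,Brown,NP,White,Smooth,Root,
DNRA4,Irregular umbonate,Off white,Off white,NP,White,Dry,Root,
DNRA5,"Irregular, raised",White,Brown,NP,White,"Rough. Spongy",Root,
DNLA1,"Irregular, umbonate",White,White,NP,White,Dry,Leaf,
DNLA2,Irregular raised,Gray,Gray,NP,Gray,"Dry, Sticky",Leaf,
DNLA13,Irregular raised,Blackish gray,Dark brown,NP,Gray,Dry,Leaf,Streptomyces
DCRA1,Circular umbonate,White,Light brown,NP,White,Dry,Root,
DCRA2,Circular raised,Off white,Gray,NP,White,Dry,Root,
DCRA3,"Undulate, flat",White,Brown,NP,White,"Rough, dry",Root,
DCLA1,Irregular raised,Off white,Light brown,NP,White,Dry,Leaf,
DCLA2,Irregular undulate,Black,Black,NP,Gray,Rough dry,Leaf,
DCLA5,"Curled, umbonate",Brown,Brown,NP,Brown,"Rough, dry",Leaf,Streptomyces
DMRA1,Irregular raised,Off white,Light cream,NP,White,Dry,Root,
DMRA2,Circular umbonate,Gray,Blackish gray,NP,Gray,Dry,Root,
DMRA3,Irregular raised,Gray,Gray,NP,Gray,Dry,Root,
DMLA8,Irregular umbonate,Off white,Off white,NP,White,Rough dry,Leaf,
DDRA1,Irregular umbonate,Cream white,Brown,NP,White,Dry,Root,
DDRA2,Circular umbonate,Brown,Brown,NP,Brown,Dry,Root,
DDRA3,Circular raised,Orange,Cream white,NP,Orange,Dry,Root,
DDRA4,"scalloped, raised",Orange,Orange,Yellow,Orange,Smooth,Root,
DDLA1,Circular pulvinate,Brownish-yellow,Light yellow,Light brown,Yellow,Dry,Leaf,
DDLA2,"Irregular, umbonate",Off white,Off white,NP,White,Dry,Leaf,
DFRA1,Irregular raised,Grey,Light brown,NP,Gray,Dry,Root,
DFRA2,Undulate raised,White,White,NP,White,Dry,Root,
DFRA3,Circular raised,Gray,Light brown,NP,Gray,Dry,Root,
DFLA1,"Circular, raised",White,Orange,yellow,White,Rough,Leaf,
DFLA4,"Curled, raised",Pink,Yellow,NP,Pink,"Rough, powdery",Leaf,
CARA1,Circular flat,Yellow,White,NP,Yellow,Dry,Root,
CARA2,"Circular, umbonate",Gray,Light brown,NP,Gray,Dry,Root,
CARA3,"Irregular, Pulvinate",White,Light brown,NP,White,Dry,Root,
CALA1,Undulate flat,Peach,Peach,NP,Orange,Dry,Root,
RRRA1,Irregular flat,Gray,Brown,NP,Gray,Dry/spongy,Root,
RRLA1,Circular umbonate,Orange,Light brown,Light brown,Orange,Dry,Leaf,
RRR46,Irregular umbonate,Off white,White,NP,White,Dry,Root,
RVRA1,Irregular convex,Red,Red,Light pink,Red,Dry,Root,
RVRA2,"Irregular, raised",Cream white,Light brown,NP,White,Dry,Root,Actinomadura
RVRA3,"Circular, umbonate",Yellow,Brown,NP,Yellow,Dry,Root,
RVRA4,"Circular, convex",Pink,Yellow,NP,Pink,Dry,Root,
RVRA6,Undulate raised,yellow,Light brown,NP,Yellow,Dry,Root,
RVRA7,"Circular, crateriform",White,white,NP,White,Rough dry,Root,Streptomyces
RVRA8,Irregular pulvinate,White,Light brown,Light brown,White,Rough dry,Root,
RVLA1,Circular convex,Dark gray,Dark brown,NP,Gray,Rough dry,Leaf,
MORA11,Irregular raised,Dark gray,Black,Black,Gray,Dry/powdery,Root,
MORA2,Circular crateriform,Light brown,Light brown,NP,Brown,Dry,Root,
MOLA1,"Irregular, pulvinate",Gray,Brown,Light brown,Gray,Dry,Leaf,
VCLA1,Circular raised,Off white,Light brown,NP,White,Dry,Leaf,
VCLA3,Undulate raised,Gray,Light brown,NP,Gray,Dry,Leaf,Streptomyces
VCRA1,Irregular umbonate,Cream white,Cream white,NP,White,Dry,Root,
VCRA2,Circular raised,White,Yellow,Yellow,White,Rough dry,Root,Streptomyces
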