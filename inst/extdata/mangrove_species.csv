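sl_no,local_name,code,scientific_name,family,iucn_status,archive_occurrences,gps_verified_points,intertidal_position
1,Tora,AR,Aegialitis rotundifolia,Plumbaginaceae,NT,35,60,low
2,Khalsi,AC,Aegiceras corniculatum,Myrsinaceae,LC,34,55,middle
3,Kalo Baine,AA,Avicennia alba,Acanthaceae,LC,45,60,low
4,Peara Baine,AM,Avicennia marina,Acanthaceae,LC,56,60,middle
5,Jat Baine,AO,Avicennia officinalis,Acanthaceae,LC,65,40,middle
6,Bakul Kankra,BG,Bruguiera gymnorrhiza,Rhizophoraceae,LC,64,80,low
7,Jhamti Garan,CD,Ceriops decandra,Rhizophoraceae,NT,50,30,low
8,Jat Garan,CT,Ceriops tagal,Rhizophoraceae,LC,38,65,low
9,Genwa,EA,Excoecaria agallocha,Euphorbiaceae,LC,25,25,mixed
10,Sundari,HF,Heritiera fomes,Malvaceae,EN,10,15,mixed
11,Goria,KC,Kandelia candel,Rhizophoraceae,LC,23,35,mixed
12,Kripa,LR,Lumnitzera racemosa,Combretaceae,LC,40,45,middle
13,Gol Pata,NF,Nypa fruticans,Arecaceae,LC,25,25,high
14,Hental,PP,Phoenix paludosa,Arecaceae,NT,36,60,mixed
15,Garjan,RM,Rhizophora mucronata,Rhizophoraceae,LC,45,47,middle
16,Tak Keora,SA,Sonneratia apetala,Lythraceae,LC,60,66,middle
17,Dhundul,XG,Xylocarpus granatum,Meliaceae,LC,36,55,mixed
18,Pashur,XM,Xylocarpus mekongensis,Meliaceae,NT,20,30,mixed
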