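species,n,habitat,SL,ABS,ABSp,ARRV,ABP,ADS,ARRD,ADP,ADR,area
Copadichromis mbenji,3,L,88.1,10.1,13.5,7.5,14.7,18.7,3.5,27.7,0.8,354.2
Cynotilapia afra,3,L,75.0,7.1,8.9,4.4,8.5,6.2,3.5,18.3,0.7,213.7
Cyrtocara moori,2,B,133.0,15.1,53.3,26.2,45.2,64.9,13.8,88.1,3.8,
Exochromis anagenys,1,L,172.2,45.2,68.5,40.7,77.0,80.3,22.4,127.0,8.3,800.6
Fossochromis rostratus,3,L,76.4,5.6,8.3,6.1,8.2,10.1,1.3,15.8,0.6,159.0
Labeotropheus fuelleborni,4,B,97.5,20.3,31.0,10.9,31.2,29.7,6.1,53.8,2.2,360.3
Labeotropheus trewavasae,3,B,86.9,7.3,13.0,4.4,10.2,14.4,2.7,20.4,2.0,192.4
Lethrinops gossei,3,B,115.2,31.9,52.0,38.6,65.7,67.7,9.7,97.8,4.6,
Maravichromis mola,2,B,113.1,16.8,35.5,19.4,30.8,50.4,9.9,66.5,2.6,
Mchenga eucinostomus,4,L,81.8,6.0,7.7,5.0,11.4,11.0,2.7,19.1,0.6,96.7
Nimbochromis polystigma,4,L,88.2,9.9,15.8,8.1,17.1,18.0,4.2,32.1,1.1,241.4
Nyassochromis prostoma,3,L,114.4,19.2,36.2,22.7,38.4,43.8,8.9,69.7,2.3,367.4
Otopharynx pictus,3,L,82.7,5.2,10.3,4.8,9.8,13.6,2.1,21.5,1.2,258.7
Petrotilapia nigra,3,B,103.4,21.0,30.8,14.6,35.8,30.5,6.8,60.5,1.9,
Placidochromis johnstonii,1,L,130.1,25.7,41.3,19.3,49.4,53.5,15.8,96.3,5.2,
Placidochromis tokolosh,1,L,145.5,26.7,16.3,27.5,48.8,55.3,8.9,83.2,5.8,
Rhamphochromis esox,1,L,119.7,4.0,7.4,3.2,7.3,10.5,1.4,13.0,0.4,
Taeniolethrinops praeorbitalis,3,B,139.0,43.3,66.7,37.0,86.5,81.2,15.7,152.8,7.4,760.0
Trematocranus placodon,3,B,131.9,29.4,52.7,30.3,51.0,66.9,18.6,103.5,6.1,
Tropheops gracilior,2,B,70.3,10.9,9.9,5.7,12.8,14.3,3.0,25.7,0.7,216.9
Tropheops orange chest,3,B,83.0,11.3,18.4,7.3,17.3,18.0,4.1,31.1,1.3,250.0
Tropheops red cheek,3,B,76.9,6.9,14.0,4.8,12.9,12.2,3.9,22.6,0.7,219.6
Tyrannochromis macrostoma,3,L,91.9,7.5,13.6,10.2,16.8,15.4,7.9,24.3,0.9,140.5
Tyrannochromis maculiceps,3,L,115.7,17.0,26.6,18.9,40.1,31.9,8.1,58.6,3.2,390.8
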