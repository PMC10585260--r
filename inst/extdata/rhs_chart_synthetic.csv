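"name","L","a","b"
"Black 202-A",11.8,2.4,0.9
"Blue 100-A",33.3,14.2,-45
"Blue 104-B",60.6,-3.3,-25.1
"Brown 200-A",34.6,9.5,19.9
"Dark-Red 59-A",24.3,37.9,13.1
"Green 125-A",35.8,-27.3,8.3
"Green 137-A",36.5,-23.4,18.5
"Green 139-A",30.6,-21.1,16.7
"Grey 201-B",56.6,0.9,3.4
"Grey-Brown 199-A",31.6,6.9,9.3
"Greyed-Green 189-A",60,-11.1,8.2
"Greyed-Green 191-A",46.8,-8.8,6.4
"Greyed-Orange 165-A",41.8,19.4,29.8
"Greyed-Purple 183-A",26.2,30.6,5.4
"Greyed-Purple 184-A",32.1,29.5,7.5
"Greyed-Purple 185-A",34.4,42,12.7
"Greyed-Purple 187-A",19.6,20.2,2.2
"Greyed-Red 178-A",37.2,36,18.3
"Greyed-Red 180-B",46.3,28.2,15.6
"Orange 25-A",68.9,29.2,62.1
"Orange-Red 30-A",58.3,47.9,51.6
"Orange-Red 34-A",54.3,55.4,42.1
"Purple 77-A",31.2,35.7,-23
"Purple-Violet 80-A",32.5,30,-33.8
"Red 42-A",47.5,61.4,36.6
"Red 45-A",41.9,59.5,35.1
"Red 46-A",37.3,54.8,31.8
"Red 53-A",30.6,47.3,22.4
"Violet 86-A",29,27.7,-39.4
"Violet-Blue 89-A",28.5,19.7,-40.3
"White 155-D",96.1,-0.9,3.5
"White 157-A",92,-0.4,4.2
"Yellow 2-A",91.3,-10.8,72.9
"Yellow 9-A",88.3,-6.6,69.7
"Yellow-Green 144-A",69.1,-27.3,55.4
"Yellow-Green 150-C",79.5,-19.2,45.3
"Yellow-Orange 15-A",81.5,6.9,69.2
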