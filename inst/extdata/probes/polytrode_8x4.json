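{"name":"polytrode_8x4","site_diameter_um":13,"sites":[[-10,0,0],[10,0,20],[-10,0,40],[10,0,60],[-10,0,80],[10,0,100],[-10,0,120],[10,0,140],[190,0,0],[210,0,20],[190,0,40],[210,0,60],[190,0,80],[210,0,100],[190,0,120],[210,0,140],[390,0,0],[410,0,20],[390,0,40],[410,0,60],[390,0,80],[410,0,100],[390,0,120],[410,0,140],[590,0,0],[610,0,20],[590,0,40],[610,0,60],[590,0,80],[610,0,100],[590,0,120],[610,0,140]]}
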