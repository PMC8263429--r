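{"shape":[32,32,32],"spacing":[1,1,1],"centers":[[20.7336892620961,11.192010477192,16.0683978739181],[7.01238870237989,10.9245885494762,22.4358510167247]],"radii":[[5.75504277739674,5.75504277739674,5.75504277739674],[4.64429455948994,4.64429455948994,4.64429455948994]]}
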