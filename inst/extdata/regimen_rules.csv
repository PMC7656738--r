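label,required,allowed_extra
VRd,bortezomib+lenalidomide+dexamethasone,
Vd,bortezomib+dexamethasone,
Rd,lenalidomide+dexamethasone,
V/alkylator,bortezomib+ALKYLATOR,dexamethasone
V,bortezomib,
R,lenalidomide,
T,thalidomide,
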