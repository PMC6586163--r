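parameter,group,mean,sd,n,units
Lpr_hydrostatic,control,8.11e-8,2.37e-8,8,m s-1 MPa-1
Lpr_hydrostatic,stress,3.19e-8,1.45e-8,8,m s-1 MPa-1
Lpr_osmotic,control,3.15e-8,3.0e-8,8,m s-1 MPa-1
Lpr_osmotic,stress,3.59e-8,1.91e-8,8,m s-1 MPa-1
Psr,control,2.24e-9,1.54e-9,8,m s-1
Psr,stress,0.61e-9,0.61e-9,8,m s-1
sigma,control,0.38,0.06,8,
sigma,stress,0.38,0.17,8,
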