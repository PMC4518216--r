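material,energy_keV,delta,mu_per_mm
water,15.0,1.025848e-06,1.673000e-01
water,16.0,9.014417e-07,1.421603e-01
water,17.0,7.983721e-07,1.219971e-01
water,18.0,7.120237e-07,1.056133e-01
water,19.0,6.389653e-07,9.214563e-02
water,20.0,5.766027e-07,8.096000e-02
nylon12,15.0,1.039707e-06,9.407516e-02
nylon12,16.0,9.137044e-07,8.250297e-02
nylon12,17.0,8.092964e-07,7.280656e-02
nylon12,18.0,7.218153e-07,6.461895e-02
nylon12,19.0,6.477903e-07,5.765524e-02
nylon12,20.0,5.845964e-07,5.169240e-02
air,15.0,1.111333e-09,1.935259e-04
air,16.0,9.765543e-10,1.642395e-04
air,17.0,8.648920e-10,1.407773e-04
air,18.0,7.713456e-10,1.217336e-04
air,19.0,6.921976e-10,1.060959e-04
air,20.0,6.246374e-10,9.312080e-05
polymer_shell,15.0,1.127850e-06,1.037496e+00
polymer_shell,16.0,9.907765e-07,8.620398e-01
polymer_shell,17.0,8.772539e-07,7.240776e-01
polymer_shell,18.0,7.821814e-07,6.140909e-01
polymer_shell,19.0,7.017678e-07,5.253236e-01
polymer_shell,20.0,6.331477e-07,4.528892e-01
gas_core,15.0,0,0
gas_core,16.0,0,0
gas_core,17.0,0,0
gas_core,18.0,0,0
gas_core,19.0,0,0
gas_core,20.0,0,0
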