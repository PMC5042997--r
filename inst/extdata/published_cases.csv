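case,mu,k1,k2,beta,kappa,m,zeta,n,xi,epsilon_percent,strain_rate,break_reported
A,1.50e-3,26.38,3.58,41.00,0.1404,NA,NA,NA,NA,11.73,0.012,no
B,1.51e-1,15.10,23.30,40.90,0.1404,3.46,3.26,6.30,1.10,4.47,0.012,no
C,1.47e-1,14.72,22.91,41.00,1.36e-3,3.30,3.27,6.33,1.11,4.49,0.012,no
D,1.52e-1,15.25,23.23,41.00,0.1404,3.15,3.23,6.33,1.10,4.50,0.012,no
E,6.11e-1,61.13,42.62,25.99,3.10e-1,4.19,3.28,7.12,1.06,3.25,0.012,no
F,1.95e-2,9.57e-1,56.33,42.63,1.68e-1,2.36,3.11,4.49,1.06,2.46,2500,no
G,4.98e-2,4.97,2.88,47.98,1.68e-1,4.45,3.83,6.13,1.26,12.18,0.01,yes
H,3.39e-1,39.96,7.66e-1,5.20e-3,2.70e-1,1.19,3.11,24.30,1.12,7.01,0.01,yes
I,1.18,12.92,1.624e-1,40.31,1.01e-1,1.39,3.27,47.15,1.26,6.95,0.03,yes
J,5.02e-1,50.22,1.53,6.96e-2,2.84e-1,1.80,3.73,56.02,1.14,8.02,0.012,yes
K,3.17e-1,285.67,216.27,46.02,1.68e-1,2.87,3.03,3.71,1.03,2.15,0.22,no
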