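# Five-Gaussian parameterization of elastic electron scattering factors for
# neutral atoms, f(q) = sum_i a_i * exp(-b_i * q^2) with q = sin(theta/2)/lambda
# in 1/Angstrom and f in Angstrom (first Born approximation, non-relativistic).
# Coefficients: L.-M. Peng, G. Ren, S. L. Dudarev, M. J. Whelan,
# Acta Cryst. A52 (1996) 257-276, Table 1 (valid for q in [0, 2] 1/Angstrom).
# version: 1
element	a1	a2	a3	a4	a5	b1	b2	b3	b4	b5
H	0.0349	0.1201	0.1970	0.0573	0.1195	0.5347	3.5867	12.3471	18.9525	38.6269
C	0.0893	0.2563	0.7570	1.0487	0.3575	0.2465	1.7100	6.4094	18.6113	50.2523
N	0.1022	0.3219	0.7982	0.8197	0.1715	0.2451	1.7481	6.1925	17.3894	48.1431
O	0.0974	0.2921	0.6910	0.6990	0.2039	0.2067	1.3815	4.6943	12.7105	32.4726
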