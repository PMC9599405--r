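# synthetic flow curve: power law k=148.89 Pa*s^n, n=0.2025, 5% log-normal noise, seed 42
shear_rate_per_s,shear_stress_Pa
0.1,100.031208199286
0.121152765862859,94.4013630192667
0.146779926762207,102.801810464831
0.177827941003892,108.326064828183
0.215443469003188,111.338176723888
0.261015721568254,112.832981820671
0.316227766016838,127.18556191089
0.383118684955729,122.021127885091
0.464158883361278,140.992185969182
0.562341325190349,132.092667524548
0.681292069057962,147.045051716954
0.825404185268019,160.562604299529
1,138.901457548067
1.21152765862859,152.646450041879
1.46779926762207,159.852890566586
1.77827941003892,172.703053941746
2.15443469003188,171.471937927681
2.61015721568254,158.327492378274
3.16227766016838,166.387794028801
3.83118684955729,208.764392959661
4.64158883361278,200.081510519339
5.62341325190349,193.223484073507
6.81292069057962,217.712012295007
8.25404185268019,242.586626947327
10,260.927067305454
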