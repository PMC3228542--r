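ppi	structural	drug_chemical	functional	all
CREBBP/TP53	0.9747	0.2234	0.9682	0.9507
E2F1/RB1	0.6162	0.4677	0.9922	0.9402
E2F2/RB1	0.8452	0.4677	0.9964	0.9000
EGFR/TGFA	0.6832	0.7028	0.9957	0.9393
EP300/TP53	0.9747	0.2234	0.9214	0.9454
GRB2/GRB2	0.9327	0.2356	0.9838	0.9058
GRB2/VAV1	0.7431	0.2234	0.9978	0.9662
HRAS/RAF1	0.5453	0.3029	0.9973	0.9140
HRAS/RALGDS	0.9320	0.2234	0.9891	0.9152
HRAS/RASA1	0.7267	0.2234	0.9988	0.9459
HRAS/SOS2	0.8991	0.2234	0.9911	0.9293
NFKB1/NFKBIA	0.8607	0.8146	0.9993	0.9343
NFKB1/RELB	0.5218	0.8146	0.9868	0.9195
RAF1/RAP1A	0.8070	0.4380	0.9937	0.9154
TP53/TP53BP2	0.2102	0.2234	0.3776	0.9274
XIAP/CASP3	0.5897	0.3679	0.9998	0.9219
XIAP/CASP9	0.7910	0.2277	0.9954	0.9468
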