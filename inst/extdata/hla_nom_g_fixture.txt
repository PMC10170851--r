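# file: hla_nom_g_fixture.txt
# synthetic desk-scale subset written in the IPD-IMGT hla_nom_g dialect
# (gene*;allele list separated by '/';G-group name, empty when singleton)
A*;01:01:01:01/01:01:01:02N/01:01:02/01:01:38L;01:01:01G
A*;02:01:01:01/02:01:01:02L/02:01:08/02:09;02:01:01G
A*;02:10;
A*;03:01:01:01/03:01:01:02N/03:01:07;03:01:01G
B*;07:02:01/07:02:06/07:61;07:02:01G
B*;57:01:01:01/57:01:01:02/57:01:03;57:01:01G
B*;57:01:07;
B*;08:01:01/08:19N;08:01:01G
C*;07:01:01:01/07:01:02/07:01:19;07:01:01G
C*;04:01:01:01/04:01:01:02/04:09N;04:01:01G
DRB1*;14:02:01/14:02:02;14:02:01G
DRB1*;15:01:01:01/15:01:01:02/15:01:01:03;15:01:01G
DQB1*;06:02:01:01/06:02:01:02;06:02:01G
DQB1*;02:01:01/02:02:01:01/02:02:01:02;02:01:01G
DPB1*;04:01:01:01/04:01:01:02/04:01:31;04:01:01G
DPB1*;23:01:01;
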