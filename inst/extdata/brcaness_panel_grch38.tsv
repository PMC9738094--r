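# BRCAness gene panel: 40 BRCAness genes plus the BRCA1/BRCA2 references.
# genome_build: GRCh38
# tss_pos: 1-based, approximate 5'-most coordinate of the canonical transcript.
# Override via the panel argument of load_cohort()/the analysis config if a
# different annotation is required.
symbol	is_reference	tss_chrom	tss_pos
ATM	FALSE	chr11	108222484
ATR	FALSE	chr3	142562757
AURKA	FALSE	chr20	58920437
BAP1	FALSE	chr3	52410024
BARD1	FALSE	chr2	214809711
BLM	FALSE	chr15	90717327
BRCA1	TRUE	chr17	43125483
BRCA2	TRUE	chr13	32315474
BRIP1	FALSE	chr17	61863558
CDK12	FALSE	chr17	39461486
CHD4	FALSE	chr12	6570082
CHEK1	FALSE	chr11	125624830
CHEK2	FALSE	chr22	28742422
EMSY	FALSE	chr11	76444011
ERCC1	FALSE	chr19	45451547
FANCA	FALSE	chr16	89816647
FANCC	FALSE	chr9	95317730
FANCD2	FALSE	chr3	10026438
FANCE	FALSE	chr6	35452337
FANCF	FALSE	chr11	22625210
FANCI	FALSE	chr15	89244692
KMT2A	FALSE	chr11	118436492
MRE11A	FALSE	chr11	94492323
MYC	FALSE	chr8	127735434
NBS1	FALSE	chr8	90003228
PALB2	FALSE	chr16	23641310
PARP1	FALSE	chr1	226408154
PAXIP1	FALSE	chr7	154957079
PLK1	FALSE	chr16	23677656
PTEN	FALSE	chr10	87863113
RAD50	FALSE	chr5	132556108
RAD51	FALSE	chr15	40694774
RAD51B	FALSE	chr14	67819779
RAD51C	FALSE	chr17	58692573
RAD51D	FALSE	chr17	35119243
RAD52	FALSE	chr12	911690
SAMHD1	FALSE	chr20	36951708
SEM1	FALSE	chr7	96649764
TP53	FALSE	chr17	7687490
TP53BP1	FALSE	chr15	43511787
WEE1	FALSE	chr11	9573761
WRN	FALSE	chr8	31033788
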