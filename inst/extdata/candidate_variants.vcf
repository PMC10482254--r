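##fileformat=VCFv4.2
##reference=GRCh37/hg19
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=CONSEQ,Number=A,Type=String,Description="Consequence class">
##INFO=<ID=AC_GNOMAD,Number=A,Type=Integer,Description="Alt allele count in gnomAD v2.1.1">
##INFO=<ID=AN_GNOMAD,Number=1,Type=Integer,Description="Allele number in gnomAD v2.1.1">
##INFO=<ID=INHOUSE,Number=1,Type=Integer,Description="In-house database occurrence count">
##INFO=<ID=PPH_S,Number=1,Type=Float,Description="Polyphen score">
##INFO=<ID=PPH_C,Number=1,Type=String,Description="Polyphen class">
##INFO=<ID=SIFT_S,Number=1,Type=Float,Description="SIFT score">
##INFO=<ID=SIFT_C,Number=1,Type=String,Description="SIFT class">
##INFO=<ID=COND_NT,Number=1,Type=String,Description="Condel nucleotide conservation">
##INFO=<ID=COND_AA,Number=1,Type=String,Description="Condel amino-acid conservation">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Total read depth">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=SS,Number=1,Type=Integer,Description="Reads with a supporting 25-bp seed">
##FORMAT=<ID=CL,Number=1,Type=Integer,Description="Clonal reads beyond the first at the start site">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	I-1	I-2	II-1	II-2	III-1	III-2
8	145066215	.	G	A	.	PASS	GENE=GRINA;CONSEQ=missense;AC_GNOMAD=2;AN_GNOMAD=282710;INHOUSE=0;PPH_S=1;PPH_C=probably_damaging;SIFT_S=0;SIFT_C=deleterious;COND_NT=highly;COND_AA=highly	GT:DP:AD:SS:CL	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1
9	125239752	rs143862742	C	T	.	PASS	GENE=OR1J1;CONSEQ=missense;AC_GNOMAD=4;AN_GNOMAD=281994;INHOUSE=0;PPH_S=0.001;PPH_C=benign;SIFT_S=0.56;SIFT_C=tolerated;COND_NT=weakly;COND_AA=highly	GT:DP:AD:SS:CL	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1
9	127990266	rs142347258	G	A	.	PASS	GENE=RABEPK;CONSEQ=missense;AC_GNOMAD=80;AN_GNOMAD=278552;INHOUSE=0;PPH_S=1;PPH_C=probably_damaging;SIFT_S=0;SIFT_C=deleterious;COND_NT=highly;COND_AA=highly	GT:DP:AD:SS:CL	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1
11	33052944	.	C	T	.	PASS	GENE=DEPDC7;CONSEQ=missense;AC_GNOMAD=0;AN_GNOMAD=249446;INHOUSE=0;PPH_S=0.896;PPH_C=possibly_damaging;SIFT_S=0.07;SIFT_C=tolerated;COND_NT=moderately;COND_AA=moderately	GT:DP:AD:SS:CL	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1
11	95712527	rs201299551	T	C	.	PASS	GENE=MAML2;CONSEQ=missense;AC_GNOMAD=95;AN_GNOMAD=279812;INHOUSE=0;PPH_S=0.998;PPH_C=probably_damaging;SIFT_S=0.06;SIFT_C=tolerated;COND_NT=moderately;COND_AA=highly	GT:DP:AD:SS:CL	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1
11	123777296	rs201007236	G	A	.	PASS	GENE=OR8D4;CONSEQ=missense;AC_GNOMAD=224;AN_GNOMAD=282640;INHOUSE=0;PPH_S=0;PPH_C=benign;SIFT_S=0;SIFT_C=deleterious;COND_NT=weakly;COND_AA=weakly	GT:DP:AD:SS:CL	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1
11	125786960	rs370049057	C	G	.	PASS	GENE=DDX25;CONSEQ=missense;AC_GNOMAD=3;AN_GNOMAD=241854;INHOUSE=0;PPH_S=0;PPH_C=benign;SIFT_S=0.49;SIFT_C=tolerated;COND_NT=weakly;COND_AA=highly	GT:DP:AD:SS:CL	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1
12	1949897	rs376597005	G	A	.	PASS	GENE=CACNA2D4;CONSEQ=splice_site;AC_GNOMAD=9;AN_GNOMAD=280408;INHOUSE=0	GT:DP:AD:SS:CL	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1
15	79614380	.	C	T	.	PASS	GENE=TMED3;CONSEQ=missense;AC_GNOMAD=3;AN_GNOMAD=282836;INHOUSE=0;PPH_S=0.773;PPH_C=possibly_damaging;SIFT_S=0.06;SIFT_C=tolerated;COND_NT=moderately;COND_AA=highly	GT:DP:AD:SS:CL	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1
17	18043906	rs200146361	C	T	.	PASS	GENE=MYO15A;CONSEQ=missense;AC_GNOMAD=513;AN_GNOMAD=280690;INHOUSE=0;PPH_S=0.999;PPH_C=probably_damaging;COND_NT=weakly;COND_AA=highly	GT:DP:AD:SS:CL	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1
20	47740944	rs201180807	T	C	.	PASS	GENE=STAU1;CONSEQ=missense;AC_GNOMAD=32;AN_GNOMAD=282876;INHOUSE=0;PPH_S=0.911;PPH_C=possibly_damaging;SIFT_S=0.33;SIFT_C=tolerated;COND_NT=weakly;COND_AA=highly	GT:DP:AD:SS:CL	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1	0/1:40:20,20:16:1	0/0:38:38,0:0:1
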