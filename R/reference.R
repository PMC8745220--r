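#' Published internal-jugular-vein differential-expression panel
#'
#' Summary statistics of the 18 disease-GWAS genes reported as
#' differentially expressed between multiple-sclerosis and control
#' internal-jugular-vein walls: per-group log2 mean and SD, regulation
#' direction, the printed absolute fold change, and the adjusted p-value.
#' Used as a validation panel: [fold_change()] applied to the printed group
#' means should round to the printed FC column (a few rows differ beyond
#' 2-dp rounding because the underlying unrounded means are unpublished).
#'
#' @return Data.frame with columns `gene`, `regulation`, `mean_ms`,
#'   `sd_ms`, `mean_c`, `sd_c`, `fc`, `p_adj`.
#' @export
ijv_de_reference <- function() {
  df <- read.csv(text = '
gene,regulation,mean_ms,sd_ms,mean_c,sd_c,fc,p_adj
AFF1,up,9.95,0.30,8.84,0.29,2.17,0.005
ALDH1L1,down,6.03,0.22,7.23,0.36,2.29,0.004
ARL11,up,3.11,0.42,2.07,0.32,2.06,0.010
BATF,up,10.52,1.39,8.94,0.46,2.99,0.049
CAMK2G,down,6.80,0.57,8.01,0.48,2.31,0.019
CD86,up,14.38,0.89,11.30,0.38,8.48,0.002
DOCK10,down,8.71,0.98,10.01,0.44,2.47,0.038
IL20RA,up,7.57,1.23,5.97,0.39,3.00,0.034
KCNIP1,up,3.84,0.66,2.65,0.70,2.28,0.042
LEF1,up,7.64,0.44,6.29,0.96,2.55,0.042
LINC01108,down,2.09,0.54,3.17,0.60,2.12,0.034
LOC100130476,up,3.33,0.15,2.16,0.35,2.24,0.047
NR1D1,up,8.31,0.97,6.45,1.16,3.63,0.042
SMARCA4,up,14.07,0.86,12.12,0.33,3.86,0.007
TEF,up,9.02,0.47,7.76,0.91,2.40,0.045
TMEM130,down,6.73,0.31,7.94,0.60,2.32,0.016
TMEM47,down,9.60,0.82,10.70,0.54,2.21,0.043
TTC28,up,8.72,0.54,7.52,0.33,2.30,0.011
', stringsAsFactors = FALSE)
  df
}

#' Published nonintronic-variant association panel
#'
#' The prioritized nonintronic variants of the combined
#' genomic-transcriptomic analysis: gene, position (GRCh38), dbSNP id,
#' tested allele, printed molecular-consequence string, and minor allele
#' frequencies in the affected Italian cohort (NIG-IT, 1098 exomes) and the
#' two control populations (1000 Genomes Tuscany; gnomAD v3.1.1
#' non-Finnish European). `arm` distinguishes disease-GWAS genes from
#' functional-partner genes. Used for fixture construction and frequency
#' sanity checks; the printed control allele numbers are not public, so the
#' printed test p-values are not recomputed from this panel.
#'
#' @return Data.frame with columns `gene`, `chrom`, `pos`, `snp_id`,
#'   `tested_allele`, `consequence`, `arm`, `maf_affected`, `maf_tsi`,
#'   `maf_nfe`.
#' @export
ijv_variant_reference <- function() {
  read.csv(text = '
gene,chrom,pos,snp_id,tested_allele,consequence,arm,maf_affected,maf_tsi,maf_nfe
DOCK10,chr2,224795011,rs113265459,A,caC/caT p.His1674His,ms_gwas,0.0224,0,0.0165
NR1D1,chr17,40100148,rs17616365,A,c.-54C > T 5-UTR,ms_gwas,0.0119,0.00485,0.0283
TMEM130,chr7,98863351,rs199556348,T,gcG/gcA p.Ala45Ala,ms_gwas,0.00046,0.00002,0.00003
GRIN2B,chr12,13611840,rs1805482,A,agC/agT p.Ser555Ser,functional_partner,0.3215,0.3786,0.3377
GRIN2B,chr12,13865843,rs7301328,C,ccC/ccG p.Pro122Pro,functional_partner,0.3646,0.4126,0.3892
PER3,chr1,7829881,rs2640908,T,acC/acT p.Thr978Thr,functional_partner,0.2044,0.2379,0.1918
PER3,chr1,7830057,rs2640909,C,aTg/aCg p.Met1037Thr,functional_partner,0.2500,0.3204,0.2872
PPARGC1A,chr4,23814301,rs2970847,C,acA/acG p.Thr394Thr,functional_partner,0.1763,0.1408,0.1923
PPARGC1A,chr4,23814039,rs8192678,T,Ggt/Agt p.Gly482Ser,functional_partner,0.3572,0.4272,0.3450
PPARGC1A,chr4,23813899,rs3755863,T,acG/acA p.Thr528Thr,functional_partner,0.4380,0.5097,0.4054
', stringsAsFactors = FALSE)
}
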