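#' AAL atlas region labels
#'
#' Returns the 116 region labels of the Automated Anatomical Labeling (AAL)
#' parcellation: 45 bilateral cerebral regions (90 labels), 9 bilateral
#' cerebellar lobules (18 labels) and 8 vermis subdivisions. These are the
#' default region names used by [generate_roi_volumes()] and the association
#' stage; any character vector of unique names may be substituted for small
#' fixtures.
#'
#' @param n Optional number of regions. `n = 116` (default) returns the AAL
#'   labels; any other value returns generic labels `ROI_001 ...` so tiny test
#'   parcellations can be built.
#' @return Character vector of `n` unique region names.
#' @export
#' @examples
#' length(aal_regions())      # 116
#' aal_regions(4)             # generic labels for a toy parcellation
aal_regions <- function(n = 116L) {
  n <- check_count(n, "n")
  if (n != 116L) return(sprintf("ROI_%03d", seq_len(n)))
  cerebrum <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf")
  cerebellum <- c(
    "Cerebelum_Crus1", "Cerebelum_Crus2", "Cerebelum_3", "Cerebelum_4_5",
    "Cerebelum_6", "Cerebelum_7b", "Cerebelum_8", "Cerebelum_9",
    "Cerebelum_10")
  vermis <- c(
    "Vermis_1_2", "Vermis_3", "Vermis_4_5", "Vermis_6", "Vermis_7",
    "Vermis_8", "Vermis_9", "Vermis_10")
  c(as.vector(t(outer(cerebrum, c("_L", "_R"), paste0))),
    as.vector(t(outer(cerebellum, c("_L", "_R"), paste0))),
    vermis)
}
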