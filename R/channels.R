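# Metal channel panel definitions.
#
# A channel panel is a data.frame with one row per acquired channel:
#   label  - unique column name used in event tables (marker name for
#            antibody channels, metal tag otherwise)
#   metal  - metal isotope tag, e.g. "Gd157"
#   mass   - integer a.m.u.
#   role   - one of tetramer_reporter, phenotype, lineage, barcode, bead,
#            dna, viability
#   marker - antibody target for phenotype/lineage channels, NA otherwise

CHANNEL_ROLES <- c("tetramer_reporter", "phenotype", "lineage", "barcode",
                   "bead", "dna", "viability")

#' Construct a metal channel panel
#'
#' @param label unique channel labels (event-table column names).
#' @param metal metal isotope tags, e.g. "Gd157".
#' @param role channel roles (see Details).
#' @param marker antibody target, NA for non-antibody channels.
#'
#' @details Roles are `tetramer_reporter` (the 9 streptavidin-coding metals),
#' `phenotype` (markers entering t-SNE/cluster analysis), `lineage` (gating
#' markers), `barcode` (Pd/Ln sample barcodes), `bead` (equilibration bead
#' metals), `dna` (iridium intercalator), `viability` (cisplatin).
#'
#' @return a `channel_panel` data.frame.
#' @export
channel_panel <- function(label, metal, role, marker = NA_character_) {
  role <- match.arg(role, CHANNEL_ROLES, several.ok = TRUE)
  x <- data.frame(label = as.character(label), metal = as.character(metal),
                  mass = as.integer(gsub("\\D", "", metal)),
                  role = role, marker = marker,
                  stringsAsFactors = FALSE)
  if (anyDuplicated(x$label))
    ct_config_error("channel panel labels must be unique: %s",
                    paste(unique(x$label[duplicated(x$label)]), collapse = ", "))
  class(x) <- c("channel_panel", "data.frame")
  x
}

#' Default 41-channel acquisition panel
#'
#' Nine lanthanide tetramer-reporter channels (the five named in the source
#' study's worked example -- Gd-157, Tb-159, Dy-163, Tm-169, Yb-173 -- plus
#' four more), six Pd/In sample-barcode channels, two equilibration-bead
#' channels, DNA intercalator, cisplatin viability, six lineage markers and
#' sixteen phenotype markers.
#'
#' @return a `channel_panel` data.frame with 41 rows.
#' @export
default_channels <- function() {
  rep_metals <- c("Eu151", "Eu153", "Gd157", "Tb159", "Dy163",
                  "Ho165", "Er167", "Tm169", "Yb173")
  bc_metals <- c("Pd102", "Pd104", "Pd106", "Pd108", "Pd110", "In113")
  lineage <- c(CD45 = "Y89", CD19 = "Nd142", TCRb = "Nd143",
               CD90 = "Nd144", CD4 = "Nd145", CD8 = "Nd146")
  pheno <- c(PD1 = "Nd148", KLRG1 = "Sm147", Sca1 = "Sm149", Tim3 = "Sm152",
             CD39 = "Sm154", CD27 = "Gd155", CD160 = "Gd156", GITR = "Gd158",
             Lag3 = "Gd160", CD25 = "Dy161", CD38 = "Dy162", CD127 = "Dy164",
             CD44 = "Er166", CD62L = "Er168", CXCR3 = "Er170", ICOS = "Yb171")
  rbind(
    channel_panel(rep_metals, rep_metals, "tetramer_reporter"),
    channel_panel(bc_metals, bc_metals, "barcode"),
    channel_panel(c("Ce140", "Lu175"), c("Ce140", "Lu175"), "bead"),
    channel_panel("Ir191", "Ir191", "dna"),
    channel_panel("Pt195", "Pt195", "viability"),
    channel_panel(names(lineage), unname(lineage), "lineage", names(lineage)),
    channel_panel(names(pheno), unname(pheno), "phenotype", names(pheno))
  )
}

#' Channel labels carrying a given role
#'
#' @param panel a `channel_panel`.
#' @param role a role string (see [channel_panel()]).
#' @return character vector of labels.
#' @export
channels_by_role <- function(panel, role) {
  role <- match.arg(role, CHANNEL_ROLES)
  panel$label[panel$role == role]
}

#' Validate a channel panel for the default workflow
#' @noRd
validate_channels <- function(panel) {
  if (length(channels_by_role(panel, "tetramer_reporter")) != 9L)
    ct_config_error("panel must carry exactly 9 tetramer_reporter channels")
  if (length(channels_by_role(panel, "barcode")) != 6L)
    ct_config_error("panel must carry exactly 6 barcode channels")
  invisible(panel)
}
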