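# Phenotype archetypes C1-C10 and the rule table that recovers them.
#
# The ten clusters are encoded as per-marker signal levels in
# {neg, low, high}. The load-bearing markers reproduce the source study's
# sequential biaxial definitions:
#   C3/C4/C5: PD-1 high, KLRG-1 neg, Sca-1 high; C3 Tim-3 neg; C4 vs C5
#             split by Tim-3/CD39 intensity (C5 = high/high); GITR high on
#             all three; Lag-3 marks the dysfunctional C4/C5.
#   C6/C10:   KLRG-1 high; split by Sca-1 (C10 Sca-1 high) and Tim-3.
#   C1/C2:    PD-1/KLRG-1/Sca-1 negative; split by CD27 (C1 high); C2
#             expresses none of the signature markers.
#   C7/C8/C9: PD-1/KLRG-1 neg, Sca-1 high; split by Tim-3 (C8) and CD160
#             (C9).
# Remaining markers are calibration choices (naive-like C1/C2 keep CD62L,
# CD127, CXCR3; tumour-experienced clusters are CD44 high).

PHENO_MARKERS <- c("PD1", "KLRG1", "Sca1", "Tim3", "CD39", "CD27", "CD160",
                   "GITR", "Lag3", "CD25", "CD38", "CD127", "CD44", "CD62L",
                   "CXCR3", "ICOS")

#' Default C1-C10 phenotype archetypes
#'
#' @return a 10 x 16 character matrix over {"neg","low","high"}; rownames
#'   C1..C10, colnames the phenotype markers.
#' @export
default_archetypes <- function() {
  m <- matrix("neg", nrow = 10, ncol = length(PHENO_MARKERS),
              dimnames = list(paste0("C", 1:10), PHENO_MARKERS))
  lev <- function(cl, ...) {
    v <- c(...)
    m[cl, names(v)] <<- unname(v)
  }
  lev("C1",  CD27 = "high", CD127 = "high", CD62L = "high", CXCR3 = "high",
       CD44 = "low", CD38 = "low")
  lev("C2",  CD127 = "high", CD62L = "high", CD44 = "low")
  lev("C3",  PD1 = "high", Sca1 = "high", CD27 = "high", GITR = "high",
       Lag3 = "low", CD39 = "low", CD25 = "low", CD38 = "high",
       CD44 = "high", ICOS = "high", CXCR3 = "low")
  lev("C4",  PD1 = "high", Sca1 = "high", Tim3 = "low", CD39 = "low",
       CD27 = "high", GITR = "high", Lag3 = "high", CD25 = "low",
       CD38 = "high", CD44 = "high", ICOS = "high")
  lev("C5",  PD1 = "high", Sca1 = "high", Tim3 = "high", CD39 = "high",
       CD27 = "high", GITR = "high", Lag3 = "high", CD25 = "high",
       CD38 = "high", CD44 = "high", ICOS = "high")
  lev("C6",  KLRG1 = "high", Tim3 = "low", CD27 = "low", GITR = "low",
       Lag3 = "low", CD38 = "low", CD44 = "high", CD127 = "low",
       CXCR3 = "low")
  lev("C7",  Sca1 = "high", CD27 = "high", CD127 = "high", CD44 = "high",
       CD62L = "low", CXCR3 = "high", CD38 = "low", ICOS = "low")
  lev("C8",  Sca1 = "high", Tim3 = "high", CD27 = "low", GITR = "low",
       Lag3 = "low", CD38 = "low", CD44 = "high", CD127 = "low",
       CXCR3 = "low", ICOS = "low")
  lev("C9",  Sca1 = "high", CD160 = "high", CD27 = "low", Lag3 = "low",
       CD38 = "low", CD44 = "high", CD127 = "low", CXCR3 = "low",
       ICOS = "low")
  lev("C10", KLRG1 = "high", Sca1 = "high", CD44 = "high", CD38 = "low",
       CD127 = "low", CXCR3 = "low")
  m
}

#' Rule-based C1-C10 classifier definition
#'
#' The default rule set mirrors the sequential biaxial gating used to
#' delineate the clusters; it is exhaustive and mutually exclusive over the
#' PD-1 x KLRG-1 x Sca-1 pattern space it defines (the one combination with
#' no cluster, PD-1+ KLRG-1- Sca-1-, maps to "unclassified").
#'
#' @return an object of class `cluster_rules` (a specification consumed by
#'   [assign_rule_clusters()]).
#' @export
default_cluster_rules <- function() {
  structure(
    list(markers = c("PD1", "KLRG1", "Sca1", "Tim3", "CD39", "CD27", "CD160")),
    class = "cluster_rules"
  )
}

# Apply the default rule logic to positivity (pos) and high-level (hi)
# logical matrices with the rule markers as columns. Returns a character
# vector of labels.
.apply_rules <- function(pos, hi) {
  lab <- rep("unclassified", nrow(pos))
  klrg <- pos[, "KLRG1"]
  pd1 <- pos[, "PD1"]
  sca <- pos[, "Sca1"]
  # KLRG-1+ cells first: C10 (Sca-1 high) vs C6
  lab[klrg & sca] <- "C10"
  lab[klrg & !sca] <- "C6"
  # PD-1+ KLRG-1- Sca-1+: C3 (Tim-3-), C5 (Tim-3/CD39 high), C4 (rest)
  sel <- !klrg & pd1 & sca
  lab[sel & !pos[, "Tim3"]] <- "C3"
  lab[sel & pos[, "Tim3"] & hi[, "Tim3"] & hi[, "CD39"]] <- "C5"
  lab[sel & pos[, "Tim3"] & !(hi[, "Tim3"] & hi[, "CD39"])] <- "C4"
  # PD-1- KLRG-1- Sca-1-: C1 (CD27+) vs C2
  sel <- !klrg & !pd1 & !sca
  lab[sel & pos[, "CD27"]] <- "C1"
  lab[sel & !pos[, "CD27"]] <- "C2"
  # PD-1- KLRG-1- Sca-1+: C9 (CD160+), C8 (Tim-3+), C7 (rest)
  sel <- !klrg & !pd1 & sca
  lab[sel & pos[, "CD160"]] <- "C9"
  lab[sel & !pos[, "CD160"] & pos[, "Tim3"]] <- "C8"
  lab[sel & !pos[, "CD160"] & !pos[, "Tim3"]] <- "C7"
  lab
}
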