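# Zone-resolved suberin monomer quantification.
#
# Suberin is an aliphatic/aromatic polyester deposited on endodermal cell
# walls (suberin lamellae).  GC-quantified monomer amounts are classified
# into substance classes, summed per root zone and treatment, and
# normalized to the endodermal surface area A = 2*pi*r*L.

.aliphatic_classes <- c("alcohol", "fatty_acid", "diacid", "omega_oh_acid")
.aromatic_classes <- c("coumaric_acid", "ferulic_acid")

# class name aliases accepted in compound labels
.class_aliases <- c(
  "alcohol" = "alcohol", "alc" = "alcohol", "primary alcohol" = "alcohol",
  "fatty acid" = "fatty_acid", "fa" = "fatty_acid", "acid" = "fatty_acid",
  "diacid" = "diacid", "dicarboxylic acid" = "diacid",
  "omega-oh acid" = "omega_oh_acid", "w-oh acid" = "omega_oh_acid",
  "oh acid" = "omega_oh_acid", "omega-hydroxy acid" = "omega_oh_acid")

#' Default root-zone scheme
#'
#' Roots are divided by relative length into three developmental zones:
#' zone A (youngest, Casparian bands only), zone B (transition, patchy
#' suberin lamellae) and zone C (mature, fully suberized endodermis).
#' For chemistry the zones are A `[0, 0.25)`, B `[0.25, 0.50)`, C
#' `[0.50, 1]`; for RNA sampling only the apical half of each zone is
#' taken: A `[0, 0.125)`, B `[0.25, 0.375)`, C `[0.50, 0.625)`.
#'
#' @param purpose `"chemistry"` (default) or `"rnaseq"`.
#' @return a data frame with columns `label`, `start_fraction`,
#'   `end_fraction` (half-open intervals on relative root length).
#' @export
zone_scheme <- function(purpose = c("chemistry", "rnaseq")) {
  purpose <- match.arg(purpose)
  if (purpose == "chemistry") {
    data.frame(label = c("A", "B", "C"),
               start_fraction = c(0, 0.25, 0.50),
               end_fraction = c(0.25, 0.50, 1.0))
  } else {
    data.frame(label = c("A", "B", "C"),
               start_fraction = c(0, 0.25, 0.50),
               end_fraction = c(0.125, 0.375, 0.625))
  }
}

#' Assign a root segment to a zone
#'
#' A segment is assigned by the zone interval containing its midpoint
#' (intervals half-open on the left, the last closed).
#'
#' @param start_fraction,end_fraction segment bounds on relative root
#'   length in `[0, 1]`.
#' @param zones a zone scheme as from [zone_scheme()].
#' @return zone label, or `NA` if the midpoint falls outside all zones.
#' @export
assign_zone <- function(start_fraction, end_fraction,
                        zones = zone_scheme("chemistry")) {
  mid <- (start_fraction + end_fraction) / 2
  vapply(mid, function(m) {
    hit <- which(m >= zones$start_fraction &
                   (m < zones$end_fraction |
                      (m <= zones$end_fraction &
                         zones$end_fraction == max(zones$end_fraction))))
    if (length(hit)) zones$label[hit[1]] else NA_character_
  }, character(1))
}

#' Classify a suberin monomer label
#'
#' Parses GC monomer labels of the form `"C<len>[:<unsat>] <class>"`
#' (e.g. `"C18:1 diacid"`, `"C24 omega-OH acid"`) or a named aromatic
#' (`"coumaric acid"`, `"ferulic acid"`).  Aliphatic classes carry a
#' chain length (C16-C26 homologues dominate); aromatics do not.
#'
#' @param compound_label character vector of labels.
#' @return a data frame with columns `compound_label`, `substance_class`,
#'   `chain_length` (NA for aromatics), `unsaturation`.
#' @examples
#' classify_monomer(c("C18:1 diacid", "C24 omega-OH acid", "ferulic acid"))
#' @export
classify_monomer <- function(compound_label) {
  one <- function(lbl) {
    norm <- tolower(trimws(lbl))
    norm <- gsub("ω", "omega", norm)        # omega glyph
    norm <- gsub("‐|‑|–", "-", norm)
    if (norm %in% c("coumaric acid", "p-coumaric acid"))
      return(list("coumaric_acid", NA_integer_, NA_integer_))
    if (norm == "ferulic acid")
      return(list("ferulic_acid", NA_integer_, NA_integer_))
    m <- regmatches(norm, regexec("^c([0-9]+)(:([0-9]+))? +(.+)$", norm))[[1]]
    if (length(m) == 0)
      stop(sprintf(
        "unknown compound label '%s'; expected 'C<len>[:<unsat>] <class>' or one of: %s",
        lbl, paste(c("coumaric acid", "ferulic acid"), collapse = ", ")),
        call. = FALSE)
    len <- as.integer(m[2])
    unsat <- if (nzchar(m[4])) as.integer(m[4]) else 0L
    cls_raw <- trimws(m[5])
    cls <- unname(.class_aliases[cls_raw])
    if (is.na(cls))
      stop(sprintf(
        "unknown substance class '%s' in label '%s'; known classes: %s",
        cls_raw, lbl, paste(unique(.class_aliases), collapse = ", ")),
        call. = FALSE)
    if (len %% 2 == 1)
      warning(sprintf("odd chain length C%d in '%s' (dominant homologues are even)",
                      len, lbl), call. = FALSE)
    list(cls, len, unsat)
  }
  parsed <- lapply(compound_label, one)
  data.frame(compound_label = compound_label,
             substance_class = vapply(parsed, `[[`, character(1), 1),
             chain_length = vapply(parsed, `[[`, integer(1), 2),
             unsaturation = vapply(parsed, `[[`, integer(1), 3))
}

#' Aggregate monomer amounts into an area-normalized composition table
#'
#' Classifies each monomer record, sums amounts per
#' (zone, treatment, replicate, class), divides by the endodermal surface
#' area of the zone (micrograms per cm^2), and adds total aliphatic
#' (the four aliphatic classes) and total aromatic (coumaric + ferulic)
#' rows.  Group summaries (mean, SD, n across replicates) are returned
#' alongside the per-replicate table.
#'
#' Aromatic totals should be interpreted cautiously: in grasses, the
#' aromatics released by transesterification are bound to many cell
#' walls, not only to suberin lamellae.
#'
#' @param records data frame with columns `compound_label`, `amount_ug`,
#'   `zone`, `treatment`, `replicate`.
#' @param areas named numeric vector of endodermal areas per zone, cm^2.
#' @return list of class `"suberin_composition"`: `per_replicate` (tidy
#'   data frame of micrograms cm^-2 per class incl. `total_aliphatic`,
#'   `total_aromatic`), `summary` (mean, sd, n per zone x treatment x
#'   class), and `notes`.
#' @export
aggregate_amounts <- function(records, areas) {
  need <- c("compound_label", "amount_ug", "zone", "treatment", "replicate")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(records$amount_ug < 0))
    stop("negative monomer amounts", call. = FALSE)
  miss <- setdiff(unique(records$zone), names(areas))
  if (length(miss))
    stop("missing endodermal area for zone(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  cls <- classify_monomer(records$compound_label)
  rec <- cbind(records, substance_class = cls$substance_class)

  agg <- stats::aggregate(amount_ug ~ zone + treatment + replicate +
                            substance_class, data = rec, FUN = sum)
  agg$amount_ug_cm2 <- agg$amount_ug / unname(areas[agg$zone])
  agg$amount_ug <- NULL

  # complete the class grid with zeros so totals are well defined
  grid <- expand.grid(zone = unique(agg$zone),
                      treatment = unique(agg$treatment),
                      replicate = unique(agg$replicate),
                      substance_class = c(.aliphatic_classes, .aromatic_classes),
                      stringsAsFactors = FALSE)
  full <- merge(grid, agg, all.x = TRUE)
  full$amount_ug_cm2[is.na(full$amount_ug_cm2)] <- 0

  totals <- function(classes, label) {
    sub <- full[full$substance_class %in% classes, ]
    tt <- stats::aggregate(amount_ug_cm2 ~ zone + treatment + replicate,
                           data = sub, FUN = sum)
    tt$substance_class <- label
    tt[names(full)]
  }
  per_rep <- rbind(full,
                   totals(.aliphatic_classes, "total_aliphatic"),
                   totals(.aromatic_classes, "total_aromatic"))
  per_rep <- per_rep[order(per_rep$zone, per_rep$treatment,
                           per_rep$substance_class, per_rep$replicate), ]
  rownames(per_rep) <- NULL

  smry <- stats::aggregate(amount_ug_cm2 ~ zone + treatment + substance_class,
                           data = per_rep,
                           FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                               n = length(x)))
  smry <- cbind(smry[1:3], as.data.frame(smry$amount_ug_cm2))
  structure(list(per_replicate = per_rep, summary = smry,
                 notes = paste("aromatic totals: interpret cautiously;",
                               "in Graminaceae aromatics are bound to all",
                               "cell walls, not only suberin lamellae")),
            class = "suberin_composition")
}

#' @export
print.suberin_composition <- function(x, ...) {
  cat("Suberin composition (micrograms per cm^2 endodermis)\n")
  print(utils::head(x$summary, 12))
  cat(sprintf("... %d summary rows; note: %s\n", nrow(x$summary), x$notes))
  invisible(x)
}

#' Relative composition of aliphatic suberin classes
#'
#' Percentages of each aliphatic class of the total aliphatic suberin,
#' per zone x treatment group (computed from the group means).
#'
#' @param composition a [aggregate_amounts()] result.
#' @return data frame with `zone`, `treatment`, `substance_class`,
#'   `percent`; percentages sum to 100 within each group.
#' @export
relative_composition <- function(composition) {
  stopifnot(inherits(composition, "suberin_composition"))
  s <- composition$summary
  ali <- s[s$substance_class %in% .aliphatic_classes, ]
  tot <- stats::aggregate(mean ~ zone + treatment, data = ali, FUN = sum)
  names(tot)[3] <- "group_total"
  out <- merge(ali[c("zone", "treatment", "substance_class", "mean")], tot)
  if (any(out$group_total == 0))
    stop("all-zero aliphatic totals in at least one group: relative composition undefined",
         call. = FALSE)
  out$percent <- 100 * out$mean / out$group_total
  out[order(out$zone, out$treatment, out$substance_class),
      c("zone", "treatment", "substance_class", "percent")]
}
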