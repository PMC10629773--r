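#' Default fine-grained feature taxonomy of the glioma molecular panel
#'
#' The routine molecular neuropathology panel covers eight coarse genetic
#' domains (IDH, MGMT, EGFR, 1p/19q, Histone, TERT, ATRX, BRAF).  Each domain
#' is fractionated into mutually exclusive fine-grained states, and the
#' wildtype/normal state of every domain is itself an explicit indicator, so
#' that a patient's panel maps losslessly onto a binary feature barcode.  The
#' default taxonomy enumerates 37 fine states: 11 IDH (wildtype plus ten point
#' mutations), 5 MGMT methylation bands, 4 EGFR amplification grades, 3
#' 1p/19q states, 3 histone states, 3 TERT states, 2 ATRX states and 6 BRAF
#' states.
#'
#' The same taxonomy ships as a user-editable config file at
#' `system.file("extdata", "default_taxonomy.yaml", package = "gliomanet")`;
#' see [read_taxonomy()].
#'
#' @return Named list mapping each coarse domain to the character vector of
#'   its fine states, the first entry being the wildtype/normal state.
#' @export
default_taxonomy <- function() {
  list(
    IDH = c("wildtype", "IDH1 G395A", "IDH1 C394T", "IDH1 C394G",
            "IDH1 C394A", "IDH1 G395T", "IDH2 G515A", "IDH2 A514T",
            "IDH2 A514G", "IDH2 G515T", "IDH1 G394T"),
    MGMT = c("unmethylated", "0-5% methylation", "5-10% methylation",
             "10-25% methylation", ">25% methylation"),
    EGFR = c("no amplification", "low amplification",
             "moderate amplification", "high amplification"),
    `1p/19q` = c("no codeletion", "1p/19q codeletion", "19q deletion"),
    Histone = c("wildtype", "Hist K27M", "Hist G34R"),
    TERT = c("wildtype", "TERT C228T", "TERT C250T"),
    ATRX = c("retained", "loss of expression"),
    BRAF = c("wildtype", "BRAF 1799 T>A", "BRAF frameshift",
             "BRAF Exon 16-9", "BRAF Exon 15-9", "BRAF Exon 16-11")
  )
}

#' Read or write a feature taxonomy as YAML
#'
#' A taxonomy is a named list: coarse domain -> character vector of fine
#' states (wildtype first).  Users may extend or replace the default; the
#' feature-graph cardinality follows the taxonomy (37 nodes by default).
#'
#' @param path File path.
#' @return `read_taxonomy` returns the taxonomy list.
#' @export
read_taxonomy <- function(path) {
  tax <- yaml::read_yaml(path)
  validate_taxonomy(tax)
  lapply(tax, as.character)
}

#' @rdname read_taxonomy
#' @param taxonomy Taxonomy list to serialize.
#' @export
write_taxonomy <- function(taxonomy, path) {
  validate_taxonomy(taxonomy)
  yaml::write_yaml(taxonomy, path)
  invisible(path)
}

validate_taxonomy <- function(taxonomy) {
  if (!is.list(taxonomy) || is.null(names(taxonomy)) ||
      any(!nzchar(names(taxonomy)))) {
    stop("taxonomy must be a named list of domains")
  }
  for (dom in names(taxonomy)) {
    states <- taxonomy[[dom]]
    if (length(states) < 1 || anyDuplicated(states)) {
      stop("taxonomy domain '", dom, "' must list distinct fine states")
    }
  }
  invisible(TRUE)
}

#' Flattened indicator names of a taxonomy
#'
#' Indicator columns are named `"<domain>: <state>"` in taxonomy order; this
#' order fixes the column order of every feature barcode.
#'
#' @param taxonomy Taxonomy list.
#' @return Character vector of indicator names.
#' @export
taxonomy_features <- function(taxonomy) {
  validate_taxonomy(taxonomy)
  unlist(lapply(names(taxonomy), function(d) {
    paste0(d, ": ", taxonomy[[d]])
  }), use.names = FALSE)
}

#' Map indicator names back to their coarse domain
#' @param taxonomy Taxonomy list.
#' @return Character vector (same length/order as [taxonomy_features()]).
#' @export
taxonomy_domains <- function(taxonomy) {
  validate_taxonomy(taxonomy)
  unlist(lapply(names(taxonomy), function(d) {
    rep(d, length(taxonomy[[d]]))
  }), use.names = FALSE)
}
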