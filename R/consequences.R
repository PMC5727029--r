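#' Functional consequences of APA regulation
#'
#' 3'UTR shortening removes the alternative UTR (aUTR) between the proximal
#' and distal PAS, and with it any miRNA target sites it contains; intronic
#' PAS activation truncates the transcript, removing protein domains encoded
#' downstream of the activated PAS. Both are assessed genomically, interval
#' against PAS position, without transcript reconstruction.
#'
#' @name consequences
NULL

#' miRNA target sites removed by 3'UTR shortening
#'
#' A site of a SHORTENED gene is REMOVED iff it lies strictly within the
#' aUTR, i.e. between the proximal and distal PAS in transcript orientation;
#' all other sites (upstream of the proximal PAS, or belonging to genes
#' without a shortening call) are RETAINED.
#'
#' @param events 3'UTR `apa_events`.
#' @param sites data.frame: chrom, strand, start, end (0-based half-open),
#'   feature_id, gene_id.
#' @return list: `sites` (input rows of event genes with a `status` column),
#'   `site_tally` (REMOVED / RETAINED counts over sites of shortened genes),
#'   `gene_tally` (shortened genes with >= 1 removed site vs with sites but
#'   none removed).
#' @export
removed_mirna_sites <- function(events, sites) {
  ev <- events[match(sites$gene_id, events$gene_id), ]
  keep <- !is.na(ev$gene_id)
  sites <- sites[keep, ]; ev <- ev[keep, ]
  a <- pmin(ev$proximal_pos, ev$distal_pos)
  b <- pmax(ev$proximal_pos, ev$distal_pos)
  # strand sanity: a site must sit on its gene's strand
  ev_strand <- ifelse(ev$distal_pos >= ev$proximal_pos, "+", "-")
  wrong <- sites$strand != ev_strand
  if (any(wrong))
    warning(sum(wrong), " site(s) on the wrong strand ignored")
  in_autr <- sites$start > a & sites$end <= b
  status <- ifelse(!wrong & ev$class == "SHORTENED" & in_autr,
                   "REMOVED", "RETAINED")
  sites$status <- status
  sh <- ev$class == "SHORTENED" & !wrong
  site_tally <- c(REMOVED = sum(status[sh] == "REMOVED"),
                  RETAINED = sum(status[sh] == "RETAINED"))
  per_gene <- tapply(status[sh] == "REMOVED", sites$gene_id[sh], any)
  gene_tally <- c(WITH_REMOVED = sum(per_gene),
                  NONE_REMOVED = sum(!per_gene))
  list(sites = sites, site_tally = site_tally, gene_tally = gene_tally)
}

#' Protein domains removed or truncated by intronic APA activation
#'
#' For an ACTIVATED gene, a domain entirely downstream (transcript
#' orientation) of the activated intronic PAS is REMOVED, a domain spanning
#' the PAS is TRUNCATED, and a domain entirely upstream is RETAINED. Domains
#' of genes without an activation call are RETAINED. Since the bar-level and
#' title-level groupings of such tallies differ in whether truncation counts
#' as loss, both tallies are reported.
#'
#' @param events INTRONIC `apa_events` (with `intronic_rep_pos`).
#' @param domains data.frame: chrom, strand, start, end (0-based half-open),
#'   feature_id, gene_id.
#' @param models a `gene_model_set` (used to warn on domains outside exons).
#' @return list: `domains` (with `status`), `domain_tally`
#'   (REMOVED/TRUNCATED/RETAINED over domains of activated genes),
#'   `domain_tally_strict` (REMOVED vs NOT_REMOVED, truncated counted as
#'   removed), `gene_tally` (activated genes with >= 1 removed-or-truncated
#'   domain vs none).
#' @export
removed_domains <- function(events, domains, models) {
  ev <- events[match(domains$gene_id, events$gene_id), ]
  keep <- !is.na(ev$gene_id)
  domains <- domains[keep, ]; ev <- ev[keep, ]
  status <- rep("RETAINED", nrow(domains))
  for (i in seq_len(nrow(domains))) {
    m <- models[[domains$gene_id[i]]]
    on_exon <- any(domains$start[i] < m$exons[, "end"] &
                     domains$end[i] > m$exons[, "start"])
    if (!on_exon) {
      warning("domain ", domains$feature_id[i], " overlaps no exon of ",
              domains$gene_id[i], "; RETAINED")
      next
    }
    if (ev$class[i] != "ACTIVATED") next
    pas <- ev$intronic_rep_pos[i]
    if (m$strand == "+") {
      status[i] <- if (domains$start[i] >= pas) "REMOVED"
        else if (domains$end[i] > pas) "TRUNCATED" else "RETAINED"
    } else {
      status[i] <- if (domains$end[i] <= pas + 1L) "REMOVED"
        else if (domains$start[i] <= pas) "TRUNCATED" else "RETAINED"
    }
  }
  domains$status <- status
  act <- ev$class == "ACTIVATED"
  tally <- table(factor(status[act], c("REMOVED", "TRUNCATED", "RETAINED")))
  strict <- c(REMOVED = sum(status[act] %in% c("REMOVED", "TRUNCATED")),
              NOT_REMOVED = sum(status[act] == "RETAINED"))
  per_gene <- tapply(status[act] != "RETAINED", domains$gene_id[act], any)
  gene_tally <- c(WITH_REMOVED = sum(per_gene), NONE_REMOVED = sum(!per_gene))
  list(domains = domains, domain_tally = tally, domain_tally_strict = strict,
       gene_tally = gene_tally)
}

#' Overlap between two gene sets
#'
#' @param set_a,set_b character vectors of gene identifiers.
#' @return list: n_a, n_b, n_overlap, percent_of_a (100 * |A intersect B| /
#'   |A|, one decimal; NA for empty A).
#' @export
gene_set_overlap <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  ov <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_overlap = ov,
       percent_of_a = if (length(a) == 0) NA_real_ else
         round(100 * ov / length(a), 1))
}
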