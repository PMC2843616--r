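#' @title Fragment-table input and validation
#' @description Fragment tables are TSV with header
#'   `domain_id  fragment_id  start_residue  end_residue  n_site  c_site  status`.
#'   `status` is one of `soluble`, `insoluble`, `not_applicable`;
#'   `n_site`/`c_site` are the cleavage-site categories `0`-`4` (0 = domain
#'   edge, 1 = linker edge domain side, 2 = linker center, 3 = linker far
#'   edge, 4 = protein terminus) or `NA` when the site was not defined.
#'   Residue coordinates are 1-based inclusive. Extra columns are ignored.
#' @param path path to a TSV file.
#' @return a validated data frame of fragment records.
#' @export
read_fragment_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    na.strings = "NA", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "")
  need <- c("domain_id", "fragment_id", "start_residue", "end_residue",
            "n_site", "c_site", "status")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("fragment table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0) stop("fragment table has a header but no rows: ", path)
  tab$start_residue <- suppressWarnings(as.integer(tab$start_residue))
  tab$end_residue <- suppressWarnings(as.integer(tab$end_residue))
  tab$n_site <- suppressWarnings(as.integer(tab$n_site))
  tab$c_site <- suppressWarnings(as.integer(tab$c_site))
  validate_fragment_records(tab[need], path = path)
}

#' Write a fragment table in the TSV dialect read by [read_fragment_table()]
#' @param records a fragment-record data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragment_table <- function(records, path) {
  records <- validate_fragment_records(records)
  out <- records
  out$n_site <- ifelse(is.na(out$n_site), "NA", as.character(out$n_site))
  out$c_site <- ifelse(is.na(out$c_site), "NA", as.character(out$c_site))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

validate_fragment_records <- function(records, path = "<records>") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  rownames(records) <- NULL
  line <- function(i) paste0(path, ", row ", i)
  bad <- which(is.na(records$domain_id) | records$domain_id == "")
  if (length(bad)) stop("empty domain_id (", line(bad[1]), ")")
  key <- paste(records$domain_id, records$fragment_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (domain_id, fragment_id): ",
         records$domain_id[dup[1]], "/", records$fragment_id[dup[1]],
         " (", line(dup[1]), ")")
  bad <- which(!records$status %in% c("soluble", "insoluble", "not_applicable"))
  if (length(bad))
    stop("unknown status '", records$status[bad[1]], "' (", line(bad[1]),
         "); expected soluble|insoluble|not_applicable")
  bad <- which(is.na(records$start_residue) | is.na(records$end_residue) |
                 records$start_residue < 1 |
                 records$end_residue < records$start_residue)
  if (length(bad))
    stop("invalid residue range (", line(bad[1]),
         "); need 1 <= start_residue <= end_residue")
  for (col in c("n_site", "c_site")) {
    v <- records[[col]]
    bad <- which(!is.na(v) & !(v %in% 0:4))
    if (length(bad))
      stop(col, " outside 0..4/NA (", line(bad[1]), ")")
  }
  records
}

#' Classify domains from their fragments' solubility outcomes
#'
#' A domain is *soluble* if at least one of its assessed fragments is
#' soluble, *non_soluble* if it has assessed fragments and all are
#' insoluble (a failed prediction), and *not_assessable* if every fragment
#' is not-applicable (expression or assessment failed). Not-applicable
#' fragments are counted in `n_na` and excluded from `n_assessed`.
#'
#' @param records fragment records (see [read_fragment_table()]).
#' @return a data frame sorted by `domain_id` with columns `domain_id`,
#'   `label`, `n_assessed`, `n_soluble`, `n_insoluble`, `n_na`.
#' @export
classify_domains <- function(records) {
  records <- validate_fragment_records(records)
  tab <- table(factor(records$domain_id),
               factor(records$status,
                      levels = c("soluble", "insoluble", "not_applicable")))
  ids <- rownames(tab) # table() sorts, giving the deterministic output order
  n_sol <- as.integer(tab[, "soluble"])
  n_ins <- as.integer(tab[, "insoluble"])
  n_na <- as.integer(tab[, "not_applicable"])
  n_ass <- n_sol + n_ins
  label <- ifelse(n_sol >= 1, "soluble",
                  ifelse(n_ass >= 1, "non_soluble", "not_assessable"))
  data.frame(domain_id = ids, label = label,
             n_assessed = as.integer(n_ass), n_soluble = as.integer(n_sol),
             n_insoluble = as.integer(n_ins), n_na = as.integer(n_na),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fragment contingency counts over solubility and domain success
#'
#' Decomposes the assessed fragments into the three non-empty cells of the
#' S/S^c x D/D^c table: soluble fragments of soluble domains
#' (`n_S_and_D`), insoluble fragments of soluble domains (`n_Sc_and_D`),
#' and fragments of non-soluble domains (`n_Sc_and_Dc`). The fourth cell,
#' soluble fragments of non-soluble domains, is structurally empty — a
#' domain with a soluble fragment is by definition soluble. Not-assessable
#' domains are excluded.
#'
#' @param records fragment records.
#' @param classifications optional output of [classify_domains()] on the
#'   same records (recomputed if omitted).
#' @return an object of class `counts_table`.
#' @export
build_counts <- function(records, classifications = NULL) {
  records <- validate_fragment_records(records)
  if (is.null(classifications)) classifications <- classify_domains(records)
  lab <- setNames(classifications$label, classifications$domain_id)
  if (!all(records$domain_id %in% names(lab)))
    stop("classifications do not cover every domain in the records")
  assessed <- records[records$status != "not_applicable", , drop = FALSE]
  dlab <- lab[assessed$domain_id]
  if (any(assessed$status == "soluble" & dlab == "non_soluble"))
    stop("internal inconsistency: soluble fragment in a non_soluble domain")
  n_S_D <- sum(assessed$status == "soluble" & dlab == "soluble")
  n_Sc_D <- sum(assessed$status == "insoluble" & dlab == "soluble")
  n_Sc_Dc <- sum(dlab == "non_soluble")
  structure(list(
    n_S_and_D = as.integer(n_S_D),
    n_Sc_and_D = as.integer(n_Sc_D),
    n_Sc_and_Dc = as.integer(n_Sc_Dc),
    n_S_and_Dc = 0L,
    n_assessed = as.integer(nrow(assessed)),
    n_domains = sum(classifications$label != "not_assessable"),
    n_domains_soluble = sum(classifications$label == "soluble")
  ), class = "counts_table")
}

#' @export
print.counts_table <- function(x, ...) {
  m <- matrix(c(x$n_S_and_D, x$n_S_and_Dc, x$n_Sc_and_D, x$n_Sc_and_Dc),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("S", "S^c"), c("D", "D^c")))
  cat(sprintf("Fragment contingency (%d assessed fragments, %d/%d soluble domains)\n",
              x$n_assessed, x$n_domains_soluble, x$n_domains))
  print(m)
  invisible(x)
}

#' Estimate model parameters from contingency counts
#'
#' Point estimates from raw counts: `p_S = n_S_and_D / n_assessed`,
#' `p_S_given_D = n_S_and_D / (n_S_and_D + n_Sc_and_D)`,
#' `p_D = (n_S_and_D + n_Sc_and_D) / n_assessed` (which equals
#' `p_S / p_S_given_D` exactly). Standard errors use the binomial formula
#' \eqn{\sqrt{p(1-p)/n}} with `n` the estimate's own denominator: the
#' total assessed-fragment count for the marginals, the soluble-domain
#' fragment count for the conditional.
#'
#' When `F_window` is given, working fragment counts for the single-copy
#' model are attached as `F = F_window`, `f = round(p_S_given_D * F_window)`
#' (a pilot tests only a few of the many candidate boundary combinations,
#' so `f` is inferred from the estimated ratio, not observed directly).
#'
#' @param counts a `counts_table` from [build_counts()].
#' @param F_window optional number of testable fragments per domain
#'   (e.g. 900 for a 30 x 30 termini window).
#' @return a [model_parameters()] object; the domain-level soluble
#'   fraction is attached as attribute `domain_fraction` and the counts as
#'   attribute `counts`.
#' @export
estimate_parameters <- function(counts, F_window = NULL) {
  stopifnot(inherits(counts, "counts_table"))
  n <- counts$n_assessed
  if (n < 1) stop("no assessed fragments: parameters cannot be estimated")
  n_D <- counts$n_S_and_D + counts$n_Sc_and_D
  if (n_D < 1) stop("no fragments in soluble domains: p(S|D) is undefined")
  p_S <- counts$n_S_and_D / n
  p_SgD <- counts$n_S_and_D / n_D
  p_D <- n_D / n
  se <- list(p_S = sqrt(p_S * (1 - p_S) / n),
             p_S_given_D = sqrt(p_SgD * (1 - p_SgD) / n_D),
             p_D = sqrt(p_D * (1 - p_D) / n))
  f <- Fv <- NULL
  if (!is.null(F_window)) {
    if (!is_count(F_window)) stop("F_window must be a positive integer")
    Fv <- as.integer(F_window)
    f <- max(1L, as.integer(round(p_SgD * Fv)))
  }
  out <- model_parameters(p_S = p_S, p_S_given_D = p_SgD, p_D = p_D,
                          f = f, F = Fv, se = se, tol = 1e-9)
  attr(out, "domain_fraction") <-
    if (counts$n_domains > 0) counts$n_domains_soluble / counts$n_domains else NA_real_
  attr(out, "counts") <- counts
  out
}

#' Lower and upper parameter limits from not-applicable records
#'
#' Fragments whose expression or assessment failed carry no solubility
#' information; bounding treats every not-applicable fragment first as
#' insoluble (lower limit) and then as soluble (upper limit), recomputing
#' domain labels and all fractions over *all* fragments and domains. With
#' no N/A records both bounds collapse onto the point estimate.
#'
#' @param records fragment records.
#' @return a list with elements `lower`, `point`, `upper`, each a list of
#'   `p_S`, `p_S_given_D`, `p_D` (fragment-marginal) and `domain_fraction`
#'   (soluble domains / all domains under that assumption).
#' @export
bounds_with_na <- function(records) {
  records <- validate_fragment_records(records)
  recode <- function(status_for_na) {
    rec <- records
    rec$status[rec$status == "not_applicable"] <- status_for_na
    cls <- classify_domains(rec)
    cts <- build_counts(rec, cls)
    n_dom <- nrow(cls)
    list(p_S = cts$n_S_and_D / cts$n_assessed,
         p_S_given_D = if (cts$n_S_and_D + cts$n_Sc_and_D > 0)
           cts$n_S_and_D / (cts$n_S_and_D + cts$n_Sc_and_D) else NA_real_,
         p_D = (cts$n_S_and_D + cts$n_Sc_and_D) / cts$n_assessed,
         domain_fraction = sum(cls$label == "soluble") / n_dom)
  }
  cls0 <- classify_domains(records)
  point <- if (any(cls0$label != "not_assessable")) {
    cts0 <- build_counts(records, cls0)
    n_ass_dom <- sum(cls0$label != "not_assessable")
    list(p_S = cts0$n_S_and_D / cts0$n_assessed,
         p_S_given_D = if (cts0$n_S_and_D + cts0$n_Sc_and_D > 0)
           cts0$n_S_and_D / (cts0$n_S_and_D + cts0$n_Sc_and_D) else NA_real_,
         p_D = (cts0$n_S_and_D + cts0$n_Sc_and_D) / cts0$n_assessed,
         domain_fraction = sum(cls0$label == "soluble") / n_ass_dom)
  } else {
    list(p_S = NA_real_, p_S_given_D = NA_real_, p_D = NA_real_,
         domain_fraction = NA_real_)
  }
  list(lower = recode("insoluble"), point = point, upper = recode("soluble"))
}

#' Solubility counts by cleavage-site category
#'
#' Tabulates assessed fragments by terminus (N or C) and cleavage-site
#' category (0-4); each fragment contributes one count per terminus whose
#' site is defined. Used to check whether the position of the cleavage
#' site within the termini window affects the soluble-fragment yield.
#'
#' @param records fragment records.
#' @return a data frame with columns `terminus`, `site`, `n_soluble`,
#'   `n_insoluble`, ordered N then C, site ascending; only observed
#'   (terminus, site) combinations appear (at most 10 rows).
#' @export
cleavage_site_summary <- function(records) {
  records <- validate_fragment_records(records)
  assessed <- records[records$status != "not_applicable", , drop = FALSE]
  rows <- list()
  for (term in c("N", "C")) {
    site_col <- if (term == "N") "n_site" else "c_site"
    for (s in 0:4) {
      sel <- !is.na(assessed[[site_col]]) & assessed[[site_col]] == s
      if (!any(sel)) next
      rows[[length(rows) + 1L]] <- data.frame(
        terminus = term, site = s,
        n_soluble = sum(assessed$status[sel] == "soluble"),
        n_insoluble = sum(assessed$status[sel] == "insoluble"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(terminus = character(), site = integer(),
                      n_soluble = integer(), n_insoluble = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Synthetic fragment table with the published pilot-screen structure
#'
#' Builds a deterministic, fully synthetic fragment table whose margins
#' reproduce a published-scale pilot dissection screen of large human
#' proteins: 36 predicted domains and 436 fragments in total, of which 24
#' domains (215 fragments) were assessed — 18 soluble domains holding 175
#' fragments (111 soluble: 6 all-soluble domains, 12 mixed) and 6
#' all-insoluble domains (40 fragments) — plus 12 not-assessable domains
#' (221 not-applicable fragments). Per-domain fragment counts within those
#' margins, residue coordinates and cleavage-site labels are invented
#' (valid but arbitrary); only the margins are faithful.
#'
#' @return a fragment-record data frame (one row per fragment).
#' @export
pilot_structure_table <- function() {
  rows <- list()
  k <- 0L
  add_domain <- function(id, n_sol, n_ins, n_na) {
    n <- n_sol + n_ins + n_na
    status <- c(rep("soluble", n_sol), rep("insoluble", n_ins),
                rep("not_applicable", n_na))
    j <- seq_len(n)
    start <- 20L + 3L * j
    data.frame(
      domain_id = id,
      fragment_id = sprintf("%s.f%02d", id, j),
      start_residue = start,
      end_residue = start + 120L + 2L * j,
      n_site = (j + k) %% 4L,          # sites cycle 0..3; 4 appears via c_site below
      c_site = ifelse((j + k) %% 20L == 0L, 4L, (j + k + 1L) %% 4L),
      status = status,
      stringsAsFactors = FALSE)
  }
  layout <- rbind(
    data.frame(id = sprintf("SOL%02d", 1:6), n_sol = 7L, n_ins = 0L, n_na = 0L),
    data.frame(id = sprintf("MIX%02d", 1:12),
               n_sol = c(rep(6L, 9), rep(5L, 3)),
               n_ins = c(6L, rep(5L, 8), rep(6L, 3)),
               n_na = 0L),
    data.frame(id = sprintf("INS%02d", 1:6),
               n_sol = 0L, n_ins = c(7L, 7L, 7L, 7L, 6L, 6L), n_na = 0L),
    data.frame(id = sprintf("NAX%02d", 1:12),
               n_sol = 0L, n_ins = 0L, n_na = c(rep(19L, 5), rep(18L, 7)))
  )
  for (i in seq_len(nrow(layout))) {
    k <- k + 7L
    rows[[i]] <- add_domain(layout$id[i], layout$n_sol[i], layout$n_ins[i], layout$n_na[i])
  }
  validate_fragment_records(do.call(rbind, rows))
}
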