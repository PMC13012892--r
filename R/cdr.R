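#' Default IMGT CDR boundaries
#'
#' Built-in loop boundaries for IMGT-numbered TCR chains: CDR1 27-38,
#' CDR2 56-65, CDR3 105-117.
#'
#' @return data.frame with columns chain, loop, start, end for both TCR
#'   chains.
#' @export
cdr_imgt_default <- function() {
  loops <- data.frame(loop = c("CDR1", "CDR2", "CDR3"),
                      start = c(27L, 56L, 105L), end = c(38L, 65L, 117L))
  out <- rbind(cbind(chain = "TCRA", loops), cbind(chain = "TCRB", loops))
  rownames(out) <- NULL
  out
}

#' Read CDR annotations from CSV
#'
#' @param path CSV with header `complex_id,chain,loop,start,end`.
#' @return data.frame of annotations (ranges must not overlap within a
#'   chain of a complex).
#' @export
read_cdr_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("complex_id", "chain", "loop", "start", "end")
  if (!all(need %in% names(df))) {
    stop("CDR CSV must have columns: ", paste(need, collapse = ", "))
  }
  for (key in split(df, paste(df$complex_id, df$chain))) {
    key <- key[order(key$start), ]
    if (nrow(key) > 1 && any(key$start[-1] <= key$end[-nrow(key)])) {
      stop("overlapping CDR ranges for ", key$complex_id[1], " ", key$chain[1])
    }
  }
  df
}

#' Contact metrics for one CDR loop
#'
#' Restricts the unified graph's edges to those joining loop residues to
#' their partner chain - the MHC helices for CDR1/CDR2, the peptide for
#' CDR3, following the usual docking convention - and reports (i) the mean
#' contact distance, (ii) the number of contacting partner residues and
#' (iii) the number of contacting CDR residues. A pooled variant counting
#' both peptide and MHC partners is also returned.
#'
#' @param g A unified `interface_graph`.
#' @param chain `"TCRA"` or `"TCRB"`.
#' @param loop `"CDR1"`, `"CDR2"` or `"CDR3"`.
#' @param start,end Loop residue range (author numbering); defaults from
#'   [cdr_imgt_default()].
#' @return List with `loop`, `chain`, `mean_contact_dist` (NA when no
#'   contacts), `n_partner_residues`, `n_cdr_residues`,
#'   `n_partner_pooled`, `n_edges`.
#' @export
loop_contact_metrics <- function(g, chain, loop, start = NULL, end = NULL) {
  stopifnot(chain %in% c("TCRA", "TCRB"), loop %in% c("CDR1", "CDR2", "CDR3"))
  if (!chain %in% g$nodes$role) stop("chain role ", chain, " absent from graph")
  if (is.null(start) || is.null(end)) {
    d <- cdr_imgt_default()
    row <- d[d$chain == chain & d$loop == loop, ]
    start <- row$start; end <- row$end
  }
  partner_role <- if (loop == "CDR3") "PEPTIDE" else "MHC"
  is_cdr <- g$nodes$role == chain & g$nodes$res_seq >= start &
    g$nodes$res_seq <= end
  pick <- function(partner) {
    if (!n_edges(g)) return(integer(0))
    i <- g$edge_index[1, ]; j <- g$edge_index[2, ]
    which((is_cdr[i] & g$nodes$role[j] == partner) |
            (is_cdr[j] & g$nodes$role[i] == partner))
  }
  eids <- pick(partner_role)
  pooled <- union(pick("PEPTIDE"), pick("MHC"))
  summarize <- function(eids, partner_roles) {
    if (!length(eids)) return(list(md = NA_real_, np = 0L, nc = 0L))
    i <- g$edge_index[1, eids]; j <- g$edge_index[2, eids]
    ends <- c(i, j)
    part <- ends[g$nodes$role[ends] %in% partner_roles]
    cdr <- ends[is_cdr[ends]]
    list(md = mean(g$edge_feats[eids, "dist"]),
         np = length(unique(part)), nc = length(unique(cdr)))
  }
  s <- summarize(eids, partner_role)
  sp <- summarize(pooled, c("PEPTIDE", "MHC"))
  list(loop = loop, chain = chain, mean_contact_dist = s$md,
       n_partner_residues = s$np, n_cdr_residues = s$nc,
       n_partner_pooled = sp$np, n_edges = length(eids))
}

#' All six CDR loop metrics for a graph
#' @param g A unified `interface_graph`.
#' @param annotations Optional data.frame (chain, loop, start, end);
#'   defaults to [cdr_imgt_default()].
#' @return data.frame, one row per (chain, loop).
#' @export
cdr_contact_table <- function(g, annotations = cdr_imgt_default()) {
  rows <- lapply(seq_len(nrow(annotations)), function(k) {
    a <- annotations[k, ]
    m <- loop_contact_metrics(g, a$chain, a$loop, a$start, a$end)
    data.frame(chain = a$chain, loop = a$loop,
               mean_contact_dist = m$mean_contact_dist,
               n_partner_residues = m$n_partner_residues,
               n_cdr_residues = m$n_cdr_residues,
               n_partner_pooled = m$n_partner_pooled)
  })
  do.call(rbind, rows)
}

#' Mann-Whitney U test and Cliff's delta
#'
#' Compares two samples with the rank-sum statistic
#' `U = #\{x_i > y_j\} + 0.5 #\{ties\}`, an exact two-sided p-value by
#' enumeration of all rank assignments when the pooled size is at most 12
#' and a tie-corrected normal approximation otherwise, and Cliff's delta
#' `(#\{x>y\} - #\{x<y\}) / (nm)` as the effect size. Effect-size bands
#' follow the |delta| < 0.147 / 0.33 / 0.474 convention.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `U`, `p_two_sided`, `cliffs_delta`, `magnitude` and
#'   `method` (`"exact"` or `"normal"`).
#' @export
compare_distributions <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y)
  gt <- sum(outer(x, y, ">"))
  lt <- sum(outer(x, y, "<"))
  ties <- n * m - gt - lt
  U <- gt + 0.5 * ties
  delta <- (gt - lt) / (n * m)
  N <- n + m
  if (N <= 12) {
    pooled <- c(x, y)
    combs <- utils::combn(N, n)
    ustat <- apply(combs, 2, function(idx) {
      xx <- pooled[idx]; yy <- pooled[-idx]
      sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
    })
    center <- n * m / 2
    p <- mean(abs(ustat - center) >= abs(U - center) - 1e-12)
    method <- "exact"
  } else {
    r <- rank(c(x, y))
    tie_counts <- table(c(x, y))
    tie_term <- sum(tie_counts^3 - tie_counts) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    z <- (U - n * m / 2)
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)  # continuity corr.
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(1, p)
    method <- "normal"
  }
  magnitude <- cut(abs(delta), c(-Inf, 0.147, 0.33, 0.474, Inf),
                   labels = c("negligible", "small", "medium", "large"))
  list(U = U, p_two_sided = p, cliffs_delta = delta,
       magnitude = as.character(magnitude), method = method)
}

#' Compare a CDR metric between experimental and predicted graphs
#'
#' @param samples_exp,samples_pred Numeric vectors of a per-complex metric
#'   (e.g. CDR3 mean contact distance) for experimentally resolved and
#'   predicted structures.
#' @param metric Name for reporting.
#' @return List combining the inputs with the [compare_distributions()]
#'   results.
#' @export
paired_comparison <- function(samples_exp, samples_pred, metric = "metric") {
  cmp <- compare_distributions(samples_exp, samples_pred)
  c(list(metric = metric, samples_exp = samples_exp,
         samples_pred = samples_pred), cmp)
}
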