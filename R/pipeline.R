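# End-to-end variant prediction: joins the amino-acid, structure and
# normalization modules into feature vectors and evaluates the joint score.

#' Predict pathogenicity for a table of variants
#'
#' Assembles the five predictors per variant — normalized MAPP score,
#' SIFT, PolyPhen-2 HumVar, side-chain heavy-atom change, relative
#' accessibility — evaluates the joint score and classifies it. All
#' intermediate features are kept in the output for auditability.
#'
#' Row-level problems (missing component score, position absent from the
#' structure with no override) are collected into the `error` column, not
#' raised; the affected row carries `NA` results.
#'
#' If the table already contains a `q` column (precomputed joint scores),
#' the function runs in classification-only mode and just applies the
#' cut-offs (a `score` column is accepted as an alias).
#'
#' @param variants Data frame with columns `variant` (or `wt`/`position`/
#'   `mut`), `mapp_raw`, `sift`, `pph2_humvar`, and optionally
#'   `rel_acc_override`; or a table with `q`/`score` for classification-only
#'   mode.
#' @param structure Optional [read_structure()] object used to compute
#'   relative accessibility at each variant position.
#' @param chain Chain identifier in `structure` holding the protein
#'   (default `"A"`).
#' @param acc_overrides Optional named numeric vector or two-column data
#'   frame (`position`, `rel_acc`) of per-position accessibility values,
#'   used where the structure lacks the residue (or instead of a structure).
#' @param domain_map Domain map for MAPP normalization.
#' @param model A [codp_model()].
#' @param t_low,t_high Classification cut-offs.
#' @param ... Engine options passed to [residue_accessibility()].
#' @return The input table extended with `mapp_norm`, `delta_heavy`,
#'   `rel_acc`, `q`, `category`, `pathogenic` and `error`.
#' @examples
#' v <- data.frame(variant = "G566R", mapp_raw = 6.2, sift = 0.01,
#'                 pph2_humvar = 0.98, rel_acc_override = 0.05)
#' predict_variants(v)
#' @export
predict_variants <- function(variants, structure = NULL, chain = "A",
                             acc_overrides = NULL,
                             domain_map = msh6_domain_map(),
                             model = codp_model(),
                             t_low = 0.56, t_high = 0.65, ...) {
  variants <- as.data.frame(variants)
  score_col <- intersect(c("q", "score"), names(variants))
  if (length(score_col)) {
    cls <- classify_impact(variants[[score_col[1L]]], t_low, t_high)
    variants$q <- cls$q
    variants$category <- cls$category
    variants$pathogenic <- cls$pathogenic
    return(variants)
  }

  if (!all(c("wt", "position", "mut") %in% names(variants))) {
    if (!"variant" %in% names(variants)) {
      stop("codp_invalid_table: need a `variant` column or `wt`/`position`/",
           "`mut` columns", call. = FALSE)
    }
    p <- parse_variant(variants$variant)
    variants$wt <- p$wt
    variants$position <- p$position
    variants$mut <- p$mut
  }
  needed <- c("mapp_raw", "sift", "pph2_humvar")
  miss <- setdiff(needed, names(variants))
  if (length(miss)) {
    stop("codp_invalid_table: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  if (is.data.frame(acc_overrides)) {
    acc_overrides <- stats::setNames(acc_overrides$rel_acc,
                                     acc_overrides$position)
  }
  res_acc <- NULL
  if (!is.null(structure)) {
    res_acc <- residue_accessibility(structure, ...)
    res_acc <- res_acc[res_acc$chain == chain, , drop = FALSE]
  }

  n <- nrow(variants)
  out <- variants
  out$mapp_norm <- NA_real_
  out$delta_heavy <- NA_integer_
  out$rel_acc <- NA_real_
  out$q <- NA_real_
  out$category <- factor(rep(NA, n),
                         levels = c("non_pathogenic", "moderate", "impaired"))
  out$pathogenic <- NA
  out$error <- NA_character_

  for (i in seq_len(n)) {
    err <- tryCatch({
      for (col in needed) {
        if (is.na(variants[[col]][i])) {
          stop("codp_missing_score: missing component score: ", col,
               call. = FALSE)
        }
      }
      out$mapp_norm[i] <- normalize_mapp(variants$mapp_raw[i],
                                         variants$position[i], domain_map)
      out$delta_heavy[i] <- delta_heavy_atoms(variants$wt[i],
                                              variants$mut[i])
      ra <- NA_real_
      ov <- variants$rel_acc_override
      if (!is.null(ov) && !is.na(ov[i])) {
        ra <- ov[i]
      } else if (!is.null(acc_overrides) &&
                 as.character(variants$position[i]) %in%
                   names(acc_overrides)) {
        ra <- acc_overrides[[as.character(variants$position[i])]]
      } else if (!is.null(res_acc)) {
        hit <- res_acc$resno == variants$position[i]
        if (!any(hit)) {
          stop("codp_missing_residue: residue ", chain,
               variants$position[i],
               " is not in the structure and no override was supplied",
               call. = FALSE)
        }
        ra <- res_acc$rel_acc[hit][1L]
      } else {
        stop("codp_missing_accessibility: no structure and no ",
             "accessibility override for position ", variants$position[i],
             call. = FALSE)
      }
      out$rel_acc[i] <- ra
      fv <- data.frame(mapp_norm = out$mapp_norm[i],
                       sift = variants$sift[i],
                       pph2_humvar = variants$pph2_humvar[i],
                       delta_heavy = out$delta_heavy[i], rel_acc = ra)
      q <- joint_score(fv, model)
      cls <- classify_impact(q, t_low, t_high)
      out$q[i] <- q
      out$category[i] <- cls$category
      out$pathogenic[i] <- cls$pathogenic
      NA_character_
    }, error = function(e) conditionMessage(e))
    out$error[i] <- err
  }
  out
}
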