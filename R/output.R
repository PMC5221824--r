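# Serialization of pathway results (JSON ranked list + TSV summary).

pathway_set_to_json_list <- function(ps) {
  lapply(seq_len(nrow(ps)), function(i) {
    steps <- ps$steps[[i]]
    gs <- ps$conserved_groups[[i]]
    list(
      rank = ps$rank[i],
      total_weight = ps$total_weight[i],
      compounds = ps$compounds[[i]],
      reactions = lapply(seq_len(nrow(steps)), function(j) {
        list(
          reaction_id = steps$reaction_id[j],
          entry_id = steps$entry_id[j],
          dg_prime_r = if (is.na(steps$dg_prime_r[j])) "missing" else steps$dg_prime_r[j],
          sim = steps$sim[j],
          weight = steps$weight[j]
        )
      }),
      conserved_groups = if (is.null(gs)) list() else {
        lapply(gs$groups, function(g) {
          list(atoms = g$atom_ids, bonds = g$bond_ids,
               size = length(g$atom_ids))
        })
      }
    )
  })
}

#' Write a pathway set to disk
#'
#' Writes the ranked pathway list as JSON (every step annotated with its
#' reaction, energy — or the string `"missing"` — similarity and weight, plus
#' the conserved groups delivered to the target) and, optionally, a
#' one-row-per-pathway TSV summary.
#'
#' @param ps A `pathway_set`.
#' @param json_path Output JSON file, or `NULL` to skip.
#' @param tsv_path Output TSV file, or `NULL` to skip.
#' @return `ps`, invisibly.
#' @export
write_pathways <- function(ps, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(ps, "pathway_set"))
  if (!is.null(json_path)) {
    jsonlite::write_json(pathway_set_to_json_list(ps), json_path,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(pathway_set_summary(ps), tsv_path)
  }
  invisible(ps)
}

pathway_set_summary <- function(ps) {
  tibble(
    rank = ps$rank,
    length = ps$n_steps,
    total_weight = ps$total_weight,
    compound_chain = vapply(ps$compounds, paste, "", collapse = ","),
    reaction_chain = vapply(ps$reactions, paste, "", collapse = ",")
  )
}
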