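#' Published population-cosinor estimates for rhythmic human serum proteins
#'
#' Loads the reference table of 13 high-abundance serum proteins reported as
#' rhythmic in a constant-routine study of 10 healthy adults (9 with a
#' 12-hour component, 6 with a 24-hour component, PLG and FGA with both):
#' gene symbol, UniProt accession, period (h), acrophase (DLMO hours, signed
#' display convention), zero-amplitude p-value, and population amplitude in
#' participant z-score units. These amplitudes are the standard worked input
#' for the power module (see [power_table()]).
#'
#' @return A data.frame with columns `gene`, `uniprot_id`, `period`,
#'   `acrophase_dlmo_h`, `p_value`, `amplitude_z` (15 rows: protein x
#'   period).
#' @examples
#' ref <- rhythmic_protein_table()
#' power_table(data.frame(protein_id = ref$gene, period = ref$period,
#'                        amplitude = ref$amplitude_z, p_value = ref$p_value))
#' @export
rhythmic_protein_table <- function() {
  path <- system.file("extdata", "serum_rhythmic_proteins.csv",
                      package = "rhythmpower", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
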