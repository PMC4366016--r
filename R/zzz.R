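.datatable.aware <- TRUE

#' @import data.table
NULL

utils::globalVariables(c(
  "token", "tf", "dl", "TF", "df", "tfn", "weight", "p_risk", "gain",
  "concept_id", "left", "right", "n", "mi", "side", "rep_len", "global_ig",
  "count", "variant", "source", ".", ".N", "N"
))
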