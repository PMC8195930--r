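#include <Rcpp.h>
#include <string>

using namespace Rcpp;

// Assemble strings from 1-based alphabet codes, concatenated per `lengths`.
// Keeps random-number generation on the R side (sample.int) so that cohort
// simulation stays reproducible from a single seed.
// [[Rcpp::export]]
CharacterVector cpp_paste_codes(IntegerVector codes, IntegerVector lengths,
                                CharacterVector alphabet) {
  int n = lengths.size();
  std::vector<char> alpha(alphabet.size());
  for (int i = 0; i < alphabet.size(); ++i) {
    const char *c = CHAR(STRING_ELT(alphabet, i));
    alpha[i] = c[0];
  }
  CharacterVector out(n);
  R_xlen_t pos = 0;
  std::string buf;
  for (int i = 0; i < n; ++i) {
    buf.assign(lengths[i], ' ');
    for (int j = 0; j < lengths[i]; ++j, ++pos) {
      buf[j] = alpha[codes[pos] - 1];
    }
    out[i] = buf;
  }
  return out;
}
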