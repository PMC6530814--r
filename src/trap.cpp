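#include <Rcpp.h>
using namespace Rcpp;

// Base encoding: A=0, C=1, G=2, T=3, N=-1 (window skipped), other=-2 (error).
static inline int encode_base(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  case 'N': case 'n': return -1;
  default: return -2;
  }
}

// Expected occupancy of one TF on one sequence: logistic binding
// probability 1 / (1 + exp(E/lambda - ln_r0)) summed over every window of
// width nrow(energies) on both strands. Windows containing N contribute 0.
// [[Rcpp::export(name = ".trap_affinity_cpp")]]
double trap_affinity_cpp(const std::string& seq, const NumericMatrix& energies,
                         double lambda, double ln_r0) {
  const int w = energies.nrow();
  const int L = (int) seq.size();
  if (energies.ncol() != 4) stop("energy matrix must have 4 columns");
  if (lambda <= 0) stop("lambda must be positive");
  if (L < w) return 0.0;

  std::vector<int> code(L);
  for (int i = 0; i < L; ++i) {
    code[i] = encode_base(seq[i]);
    if (code[i] == -2)
      stop("invalid character '%s' at position %d (expected A/C/G/T/N)",
           std::string(1, seq[i]).c_str(), i + 1);
  }

  // Reverse-strand energy of a window equals scoring the same forward window
  // with the reverse-complemented matrix.
  NumericMatrix erc(w, 4);
  for (int j = 0; j < w; ++j)
    for (int b = 0; b < 4; ++b)
      erc(j, b) = energies(w - 1 - j, 3 - b);

  double aff = 0.0;
  const int nwin = L - w + 1;
  for (int i = 0; i < nwin; ++i) {
    bool ok = true;
    double ef = 0.0, er = 0.0;
    for (int j = 0; j < w; ++j) {
      const int b = code[i + j];
      if (b < 0) { ok = false; break; }
      ef += energies(j, b);
      er += erc(j, b);
    }
    if (!ok) continue;
    aff += 1.0 / (1.0 + std::exp(ef / lambda - ln_r0));
    aff += 1.0 / (1.0 + std::exp(er / lambda - ln_r0));
  }
  return aff;
}
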