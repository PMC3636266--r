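#include <Rcpp.h>
using namespace Rcpp;

// For each seed, report which subject sequences contain it at any offset with
// at most max_mismatch mismatches. 'N' (on either side) never matches. The
// inner loop aborts a position as soon as the mismatch budget is exceeded and
// a subject as soon as one qualifying offset is found (the unit of assignment
// is the subject, not the offset).
// [[Rcpp::export]]
List seed_hits_cpp(CharacterVector seeds, CharacterVector subjects,
                   int max_mismatch) {
  const int n_read = seeds.size();
  const int n_sub = subjects.size();
  std::vector<std::string> subs(n_sub);
  for (int j = 0; j < n_sub; ++j) subs[j] = as<std::string>(subjects[j]);
  List out(n_read);
  for (int i = 0; i < n_read; ++i) {
    if (i % 8192 == 0) Rcpp::checkUserInterrupt();
    SEXP se = STRING_ELT(seeds, i);
    const char* s = CHAR(se);
    const int ls = LENGTH(se);
    std::vector<int> hits;
    for (int j = 0; j < n_sub; ++j) {
      const std::string& sub = subs[j];
      const int lim = (int)sub.size() - ls;
      bool hit = false;
      for (int p = 0; p <= lim && !hit; ++p) {
        int mm = 0;
        const char* t = sub.data() + p;
        for (int k = 0; k < ls; ++k) {
          const char a = s[k], b = t[k];
          if (a != b || a == 'N') {
            if (++mm > max_mismatch) break;
          }
        }
        if (mm <= max_mismatch) hit = true;
      }
      if (hit) hits.push_back(j + 1);
    }
    out[i] = IntegerVector(hits.begin(), hits.end());
  }
  return out;
}
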