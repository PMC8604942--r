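#include <Rcpp.h>
using namespace Rcpp;

// Watson-Crick complement lookup; 0 = cannot pair (N or invalid)
static inline const unsigned char *comp_table() {
  static unsigned char tab[256];
  static bool init = false;
  if (!init) {
    memset(tab, 0, sizeof(tab));
    tab[(unsigned char) 'A'] = 'T';
    tab[(unsigned char) 'T'] = 'A';
    tab[(unsigned char) 'C'] = 'G';
    tab[(unsigned char) 'G'] = 'C';
    init = true;
  }
  return tab;
}

// Scan one ungapped, upper-case sequence for maximal perfect inverted repeats.
//
// An IR is parameterised by the spacer interval [s, e) (e - s = spacer length
// g) and the arm length a: left arm [s-a, s), right arm [e, e+a).  For each
// spacer placement the arms are extended outward while the bases pair
// (Watson-Crick; N never pairs), which makes the reported arm maximal
// outward.  A hit is dropped when the arms could also extend inward
// (seq[e-1] pairs with seq[s] and the spacer has >= 2 bases): that palindrome
// is reported at its inner, longer-armed placement instead, so every
// reported IR has arms that are not extendable on either side.
//
// Returns a matrix with columns: left_start, arm_len, spacer_len (0-based).
// [[Rcpp::export(name = ".ir_scan_c")]]
IntegerMatrix ir_scan_c(std::string seq, int min_arm, int max_spacer) {
  const unsigned char *comp = comp_table();
  const int L = (int) seq.size();
  const unsigned char *q = (const unsigned char *) seq.data();
  std::vector<int> ls, al, sl;
  for (int s = 1; s < L; ++s) {
    const unsigned char c1 = comp[q[s - 1]];   // needed at q[e] for a >= 1
    if (!c1) continue;
    const unsigned char cs = comp[q[s]];       // inward-extension partner
    const int gmax = std::min(max_spacer, L - 1 - s);
    for (int g = 0; g <= gmax; ++g) {
      const int e = s + g;
      if (q[e] != c1) continue;
      if (g >= 2 && cs && q[e - 1] == cs) continue;   // inward-extendable
      int a = 1;
      while (s - a - 1 >= 0 && e + a < L) {
        const unsigned char c = comp[q[s - a - 1]];
        if (!c || q[e + a] != c) break;
        ++a;
      }
      if (a >= min_arm) {
        ls.push_back(s - a);
        al.push_back(a);
        sl.push_back(g);
      }
    }
  }
  IntegerMatrix out((int) ls.size(), 3);
  for (int i = 0; i < (int) ls.size(); ++i) {
    out(i, 0) = ls[i];
    out(i, 1) = al[i];
    out(i, 2) = sl[i];
  }
  colnames(out) = CharacterVector::create("left_start", "arm_len", "spacer_len");
  return out;
}

// Maximal runs of contiguous substituted columns between two equal-length
// sequences.  A column counts as substituted when both characters are plain
// bases (A/C/G/T) and differ; gap or N columns break runs.  Runs shorter
// than min_run are dropped.  Returns columns: start (0-based), length.
// [[Rcpp::export(name = ".mnm_runs_c")]]
IntegerMatrix mnm_runs_c(std::string child, std::string parent, int min_run) {
  if (child.size() != parent.size()) stop("sequence length mismatch");
  const int L = (int) child.size();
  auto is_base = [](char c) {
    return c == 'A' || c == 'C' || c == 'G' || c == 'T';
  };
  std::vector<int> st, ln;
  int run = 0;
  for (int i = 0; i <= L; ++i) {
    bool sub = i < L && is_base(child[i]) && is_base(parent[i]) &&
               child[i] != parent[i];
    if (sub) {
      ++run;
    } else if (run > 0) {
      if (run >= min_run) { st.push_back(i - run); ln.push_back(run); }
      run = 0;
    }
  }
  IntegerMatrix out((int) st.size(), 2);
  for (int i = 0; i < (int) st.size(); ++i) {
    out(i, 0) = st[i];
    out(i, 1) = ln[i];
  }
  colnames(out) = CharacterVector::create("start", "length");
  return out;
}
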