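#include <Rcpp.h>
#include <unordered_map>
#include <vector>

// Non-sequential Recursive Pair Substitution (NSRPS) engine behind the
// Effort-To-Compress measure. Each pass counts adjacent symbol pairs with
// non-overlapping left-to-right counting (so "111" contains "11" once),
// replaces every non-overlapping occurrence of the winning pair with a fresh
// symbol, and repeats until the sequence is constant or of length 1. Ties in
// pair frequency go to the pair whose first occurrence is leftmost.

namespace {

struct PairStat {
  long long key;
  int count;
  std::size_t first;
};

// Most frequent adjacent pair of `s` (symbols encoded as non-negative
// integers < base), leftmost-first tie-break. Returns false if all symbols
// are equal (nothing to compress).
bool best_pair(const std::vector<long long>& s, long long base,
               long long& pa, long long& pb) {
  std::unordered_map<long long, std::size_t> slot;
  std::vector<PairStat> stats;
  std::unordered_map<long long, std::size_t> last_end;  // one past last counted occurrence
  for (std::size_t i = 0; i + 1 < s.size(); ++i) {
    long long key = s[i] * base + s[i + 1];
    std::unordered_map<long long, std::size_t>::iterator le = last_end.find(key);
    if (le != last_end.end() && le->second > i) continue;  // overlaps counted occurrence
    last_end[key] = i + 2;
    std::unordered_map<long long, std::size_t>::iterator sl = slot.find(key);
    if (sl == slot.end()) {
      slot[key] = stats.size();
      PairStat ps; ps.key = key; ps.count = 1; ps.first = i;
      stats.push_back(ps);
    } else {
      ++stats[sl->second].count;
    }
  }
  bool found = false;
  int best_count = 0;
  std::size_t best_first = 0;
  long long best_key = 0;
  for (std::size_t k = 0; k < stats.size(); ++k) {
    const PairStat& ps = stats[k];
    bool better = ps.count > best_count ||
                  (ps.count == best_count && ps.first < best_first);
    if (!found || better) {
      found = true;
      best_count = ps.count;
      best_first = ps.first;
      best_key = ps.key;
    }
  }
  if (!found) return false;
  pa = best_key / base;
  pb = best_key % base;
  return true;
}

bool is_constant(const std::vector<long long>& s) {
  for (std::size_t i = 1; i < s.size(); ++i)
    if (s[i] != s[0]) return false;
  return true;
}

long long max_sym(const std::vector<long long>& s) {
  long long m = 0;
  for (std::size_t i = 0; i < s.size(); ++i)
    if (s[i] > m) m = s[i];
  return m;
}

}  // namespace

// [[Rcpp::export(name = ".etc_steps")]]
int etc_steps_cpp(Rcpp::IntegerVector seq) {
  std::vector<long long> s(seq.begin(), seq.end());
  if (s.size() < 2) Rcpp::stop("sequence must have length >= 2");
  int steps = 0;
  while (s.size() > 1 && !is_constant(s)) {
    long long base = max_sym(s) + 1;
    long long pa = 0, pb = 0;
    best_pair(s, base, pa, pb);
    long long fresh = base;  // max(alphabet) + 1
    std::vector<long long> out;
    out.reserve(s.size());
    for (std::size_t i = 0; i < s.size();) {
      if (i + 1 < s.size() && s[i] == pa && s[i + 1] == pb) {
        out.push_back(fresh);
        i += 2;
      } else {
        out.push_back(s[i]);
        ++i;
      }
    }
    s.swap(out);
    ++steps;
  }
  return steps;
}

// Joint NSRPS on an aligned pair: positions carry symbol tuples
// (x[i], y[i]); the most frequent adjacent tuple-pair is replaced in both
// sequences simultaneously by fresh per-sequence symbols. Halts when the
// tuple sequence is constant (no two aligned pairs differ) or length 1,
// which makes the step count identical to single-sequence NSRPS on any
// bijective tuple fusion of x and y.
// [[Rcpp::export(name = ".etc_joint_steps")]]
int etc_joint_steps_cpp(Rcpp::IntegerVector xseq, Rcpp::IntegerVector yseq) {
  if (xseq.size() != yseq.size()) Rcpp::stop("sequences must have equal length");
  std::vector<long long> x(xseq.begin(), xseq.end());
  std::vector<long long> y(yseq.begin(), yseq.end());
  if (x.size() < 2) Rcpp::stop("sequence must have length >= 2");
  int steps = 0;
  for (;;) {
    std::size_t n = x.size();
    if (n <= 1) break;
    long long bx = max_sym(x) + 1;
    long long by = max_sym(y) + 1;
    // fuse tuples so the generic pair counter applies
    std::vector<long long> fused(n);
    for (std::size_t i = 0; i < n; ++i) fused[i] = x[i] * by + y[i];
    if (is_constant(fused)) break;
    long long base = bx * by;
    long long pa = 0, pb = 0;
    best_pair(fused, base, pa, pb);
    long long pax = pa / by, pay = pa % by;
    long long pbx = pb / by, pby = pb % by;
    std::vector<long long> ox, oy;
    ox.reserve(n);
    oy.reserve(n);
    for (std::size_t i = 0; i < n;) {
      if (i + 1 < n && x[i] == pax && y[i] == pay &&
          x[i + 1] == pbx && y[i + 1] == pby) {
        ox.push_back(bx);  // fresh symbol in each sequence
        oy.push_back(by);
        i += 2;
      } else {
        ox.push_back(x[i]);
        oy.push_back(y[i]);
        ++i;
      }
    }
    x.swap(ox);
    y.swap(oy);
    ++steps;
  }
  return steps;
}
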