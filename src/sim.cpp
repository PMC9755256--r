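#include <Rcpp.h>
using namespace Rcpp;

// One weighted draw over m behaviours from noisily perceived expresser
// counts: weight_j = max(0, Normal(count_j, noise)); uniform when every
// perceived weight is zero. With noise = 0 the weights are the counts.
static int draw_weighted(const std::vector<double>& cnt, double noise,
                         std::vector<double>& wbuf) {
  int m = cnt.size();
  double tot = 0.0;
  for (int j = 0; j < m; ++j) {
    double w = (noise > 0.0) ? R::rnorm(cnt[j], noise) : cnt[j];
    if (w < 0.0) w = 0.0;
    wbuf[j] = w;
    tot += w;
  }
  if (tot <= 0.0) {
    int b = (int)(unif_rand() * m);
    return b >= m ? m - 1 : b;
  }
  double u = unif_rand() * tot, acc = 0.0;
  for (int j = 0; j < m; ++j) {
    acc += wbuf[j];
    if (u <= acc) return j;
  }
  return m - 1;
}

static int draw_uniform(int m) {
  int b = (int)(unif_rand() * m);
  return b >= m ? m - 1 : b;
}

// Full trajectory of one population: t_max monthly steps of demography
// followed by one innovation opportunity per agent (random category order,
// stop at the first successful new addition). Same model semantics as the
// R engine; RNG draws are ordered per agent instead of per vector, so the
// two engines agree in distribution, not draw for draw.
// [[Rcpp::export(name = ".sim_site_cpp")]]
List sim_site_cpp(int n, int t_max,
                  NumericVector gate_social, NumericVector gate_food,
                  IntegerVector sub_idx_s, IntegerVector sub_idx_f,
                  LogicalVector nut_y,
                  int n_social_sub, int n_food_sub,
                  double S, double sigma, double peer_noise,
                  int death_onset, double death_hazard, int max_age,
                  int init_max_age) {
  const int ms = gate_social.size(), mf = gate_food.size();
  const int n_beh = ms + mf;

  IntegerVector age(n);
  LogicalMatrix rep(n, n_beh);
  std::vector<std::vector<int>> sub_s(n, std::vector<int>(n_social_sub, 0));
  std::vector<std::vector<int>> sub_f(n, std::vector<int>(n_food_sub, 0));
  std::vector<double> cnt_s(ms, 0.0), cnt_f(mf, 0.0);
  std::vector<double> snap_s(ms), snap_f(mf), wbuf(std::max(ms, mf));

  for (int i = 0; i < n; ++i) {
    age[i] = (int)(unif_rand() * init_max_age);
    if (age[i] >= init_max_age) age[i] = init_max_age - 1;
  }

  for (int t = 0; t < t_max; ++t) {
    // demography: age, die, replace by newborns in place
    for (int i = 0; i < n; ++i) {
      age[i] += 1;
      bool dead = (age[i] >= death_onset && unif_rand() < death_hazard) ||
                  age[i] > max_age;
      if (dead) {
        age[i] = 0;
        for (int j = 0; j < ms; ++j)
          if (rep(i, j)) { cnt_s[j] -= 1.0; rep(i, j) = FALSE; }
        for (int j = 0; j < mf; ++j)
          if (rep(i, ms + j)) { cnt_f[j] -= 1.0; rep(i, ms + j) = FALSE; }
        std::fill(sub_s[i].begin(), sub_s[i].end(), 0);
        std::fill(sub_f[i].begin(), sub_f[i].end(), 0);
      }
    }

    // frequency snapshot: every agent sees the same start-of-step counts
    snap_s = cnt_s;
    snap_f = cnt_f;

    for (int i = 0; i < n; ++i) {
      int fulfilled_s = 0;
      for (int k = 0; k < n_social_sub; ++k)
        if (sub_s[i][k] > 0) ++fulfilled_s;
      double st_s = (double)fulfilled_s / n_social_sub;

      int f_tot = 0, f_y = 0;
      for (int k = 0; k < n_food_sub; ++k)
        if (sub_f[i][k] > 0) { ++f_tot; if (nut_y[k]) ++f_y; }
      double st_f = (f_tot - std::abs(2 * f_y - f_tot)) / (double)n_food_sub;

      // runif < p is unaffected by clamping p into [0, 1]
      bool try_s = unif_rand() < R::rnorm(1.0 - st_s, sigma);
      bool try_f = unif_rand() < R::rnorm(1.0 - st_f, sigma);
      if (!try_s && !try_f) continue;
      bool social_first = unif_rand() < 0.5;

      for (int pass = 0; pass < 2; ++pass) {
        bool social = (pass == 0) == social_first;
        if (social ? !try_s : !try_f) continue;
        int b;
        bool mediated = unif_rand() < S;
        if (social) {
          b = mediated ? draw_weighted(snap_s, peer_noise, wbuf) : draw_uniform(ms);
          if (unif_rand() < gate_social[b] && !rep(i, b)) {
            rep(i, b) = TRUE;
            sub_s[i][sub_idx_s[b] - 1] += 1;
            cnt_s[b] += 1.0;
            break;
          }
        } else {
          b = mediated ? draw_weighted(snap_f, peer_noise, wbuf) : draw_uniform(mf);
          if (unif_rand() < gate_food[b] && !rep(i, ms + b)) {
            rep(i, ms + b) = TRUE;
            sub_f[i][sub_idx_f[b] - 1] += 1;
            cnt_f[b] += 1.0;
            break;
          }
        }
      }
    }
  }

  return List::create(_["age"] = age, _["rep"] = rep);
}
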