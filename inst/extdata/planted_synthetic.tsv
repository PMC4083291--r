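gene_id	s1	s2	s3	s4	s5	s6	s7	s8	s9	s10
g1	1.94570e-01	-6.58752e-02	-2.56411e-01	-7.71601e-02	-1.62154e-01	-9.34128e-03	5.53321e-02	1.53756e-02	-1.74053e-01	8.48416e-02
g2	-1.95212e-01	-5.59690e-02	7.46296e-02	2.06086e-01	1.52459e-01	-1.29016e-02	2.89887e-02	9.19049e-02	-6.43302e-02	-6.19024e-02
g3	-5.18681e-02	-1.46073e-01	-4.83311e-02	-1.35207e-01	-1.39883e-01	-1.80912e-01	3.08340e-02	-4.80256e-02	-5.43060e-02	-6.18380e-02
g4	2.02488e-02	9.24787e-01	1.97045e+00	3.11994e+00	5.14836e-02	5.80466e-02	-2.45675e-02	-3.99017e-02	4.04913e+00	5.01655e+00
g5	5.59215e-02	9.08791e-01	1.90760e+00	3.17487e+00	-4.60225e-02	-3.04871e-02	-4.03230e-02	1.16553e-01	4.01027e+00	4.98224e+00
g6	2.09601e-02	1.44991e-01	-1.17211e-01	-1.97971e-01	1.89005e-01	-4.46975e-02	-5.94214e-02	1.70238e-01	-9.00552e-02	1.64481e-01
g7	-1.03575e-01	-9.41828e-02	4.33392e-03	6.08800e-02	5.01807e-02	-1.12275e-01	8.01737e-03	1.60592e-01	8.68608e-03	1.18034e-01
g8	4.53261e-02	-2.28346e-01	-2.90278e-01	1.25854e-01	-1.16500e-01	3.09780e-02	4.78133e-02	1.97539e-02	1.65849e-02	4.18444e-04
g9	1.54301e-01	-1.02774e-01	-7.10466e-02	-1.21177e-02	9.09949e-03	4.53873e-02	2.82400e-02	1.12560e-01	-9.78574e-02	-8.28220e-02
g10	1.86034e-02	1.87813e-01	1.24666e-01	-1.58957e-02	-1.54451e-02	-1.26876e-01	-8.04915e-02	-1.87122e-01	-9.28661e-03	-8.97695e-02
g11	4.61568e-03	9.39029e-01	1.96359e+00	2.80744e+00	3.43484e-02	9.52494e-02	-1.37105e-01	1.52855e-01	4.13097e+00	4.77028e+00
g12	5.47269e-02	8.35309e-02	-2.23787e-02	1.44440e-01	5.39102e-02	2.96749e-02	1.16666e-01	4.94009e-02	6.99391e-02	4.91984e-04
g13	-1.18274e-01	1.56851e-01	1.01232e-01	2.88501e-05	1.26150e-01	-7.89221e-02	1.48232e-02	-2.79554e-02	2.66388e-02	-1.48626e-02
g14	-8.43905e-03	1.68541e-01	-6.38001e-02	4.70891e-02	1.21254e-01	1.19604e-01	-1.60658e-01	8.94172e-02	9.87405e-04	5.21344e-03
g15	6.40269e-02	6.78553e-02	8.03589e-02	5.34485e-02	1.24119e-01	-1.89855e-02	1.15063e-01	-1.99499e-02	-1.45475e-01	-1.49371e-01
g16	2.54123e-01	9.42363e-01	2.18426e+00	3.07072e+00	2.49934e-02	5.68483e-02	-2.07999e-02	-8.91795e-02	4.13692e+00	4.95804e+00
g17	-1.27480e-01	8.43173e-01	2.21779e+00	3.08481e+00	-6.43283e-02	1.05734e-01	5.46477e-02	-5.61094e-02	4.02921e+00	4.97881e+00
g18	7.48650e-02	-4.79208e-02	8.36783e-02	8.32713e-02	-4.16196e-02	1.23254e-01	-4.65113e-02	9.94807e-02	6.61242e-02	-1.44074e-01
g19	-2.69050e-01	3.38660e-02	-1.17727e-01	-1.00032e-01	-2.65650e-02	9.43322e-03	1.20187e-01	1.04093e-01	-9.10857e-02	1.25250e-01
g20	-1.88122e-01	3.86318e-02	-1.90919e-01	5.73616e-02	-3.50980e-02	-8.49566e-02	-6.45423e-02	-6.92056e-02	-8.32737e-02	-4.86226e-02
g21	-8.97973e-02	3.64805e-02	-1.91478e-02	3.89292e-02	5.54150e-03	-4.00277e-02	9.86234e-02	-7.55118e-04	-2.98571e-03	-8.61950e-02
g22	-2.10476e-02	-1.21058e-01	5.27576e-02	-8.10026e-02	1.22120e-01	-1.14874e-01	-2.65374e-02	7.39919e-02	5.24039e-03	-1.54766e-01
g23	-2.84806e-02	-1.16650e-01	7.53810e-02	3.49436e-02	-8.71195e-02	2.45154e-02	-4.01261e-02	8.36607e-03	-3.51201e-03	6.55473e-02
g24	1.17702e-01	-9.76981e-02	2.13099e-02	-6.39481e-02	1.51089e-01	5.59471e-02	2.82282e-02	-6.10931e-02	1.78996e-01	7.31678e-02
g25	9.64188e-02	-1.12661e-01	-1.25322e-01	-1.06105e-01	1.03209e-02	7.94360e-02	-2.18018e-01	-2.42108e-01	-9.16410e-02	1.04276e-01
g26	1.21586e-01	-7.72241e-02	4.80469e-02	-1.30138e-01	7.45434e-02	7.78324e-02	3.71961e-02	-1.66712e-02	1.28747e-01	4.96135e-02
g27	1.35374e-01	7.14895e-03	-1.00158e-01	-2.15836e-01	-8.07736e-03	-1.24977e-02	2.84305e-02	-3.68531e-02	1.20931e-01	2.50967e-02
g28	6.48425e-02	9.71253e-02	-2.05666e-02	3.91785e-02	-1.57001e-01	-3.52033e-05	-1.87395e-02	3.29730e-02	-1.16889e-01	-6.53396e-02
g29	-4.28512e-02	8.26074e-02	-1.28349e-02	1.01686e-03	-2.83034e-02	1.78901e-02	1.33985e-01	-1.67868e-02	-2.90223e-03	5.40693e-02
g30	3.39123e-02	1.74566e-01	-4.86586e-02	6.01045e-02	3.17845e-01	-2.54247e-02	-2.13628e-02	-1.67466e-02	2.39800e-02	7.64458e-02
g31	1.76376e-01	-6.93193e-02	-4.44948e-02	-1.03523e-01	5.21689e-02	-1.66049e-01	7.77938e-02	-2.42798e-02	1.67618e-02	9.57917e-02
g32	-3.57283e-02	9.15148e-01	2.25841e+00	2.99422e+00	3.50615e-02	2.74027e-02	4.40546e-02	-3.15103e-02	4.26926e+00	5.12796e+00
g33	1.55037e-01	9.00550e-01	1.83412e+00	3.13927e+00	5.48356e-02	7.46952e-03	2.16458e-02	2.36332e-02	3.81377e+00	5.08695e+00
g34	-1.37710e-02	1.06666e+00	1.93410e+00	2.89084e+00	-2.03677e-01	-7.12598e-02	8.03116e-02	-2.36906e-02	4.00331e+00	5.01144e+00
g35	2.40125e-01	8.94518e-02	4.78286e-02	-3.13595e-03	-9.11517e-02	-5.85317e-02	1.38201e-01	1.13254e-01	7.52957e-02	3.70658e-02
g36	-9.35974e-02	9.32883e-01	2.09564e+00	3.08268e+00	-8.40818e-02	-1.14457e-01	-1.42932e-01	-4.61553e-02	4.08425e+00	5.01329e+00
g37	1.76823e-01	3.38326e-03	1.13189e-01	8.28336e-04	3.16986e-02	2.99379e-02	4.75646e-02	3.52277e-02	4.37471e-02	-4.08058e-02
g38	1.06786e-02	9.44423e-01	1.91893e+00	3.07948e+00	-5.11706e-02	3.15703e-02	-7.80301e-02	-3.21905e-02	3.93313e+00	4.94092e+00
g39	-1.36378e-01	5.85562e-03	9.68249e-02	1.54987e-01	-6.44804e-02	-6.99326e-02	3.80450e-02	-1.83728e-02	-5.29165e-02	4.79187e-02
g40	-2.61034e-01	5.92934e-02	-8.49730e-02	-1.38806e-01	6.28518e-03	5.93272e-02	7.46358e-02	-1.23546e-02	3.94878e-03	9.53675e-03
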